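test_that("config validation enforces rates, fractions and geometry", {
  expect_s4_class(simConfig(), "SimulationConfig")
  expect_error(simConfig(labelingEfficiency = 1.2), "fraction")
  expect_error(simConfig(channelFootprint = 0), "channelFootprint")
  expect_error(simConfig(localizationSigma = -1), "localizationSigma")
  expect_error(simConfig(gapRange = c(100, 160)), "gapRange")
  expect_error(simConfig(interGroupSep = 100), "interGroupSep")
  ## jointly infeasible within-fraction / mean-members
  expect_error(simConfig(withinFraction = 0.2, meanMembers = 2.18),
               "infeasible")
})

test_that("cluster-size mixture pins the configured median and mean", {
  sd0 <- solveSizeDist(median = 4, mean = 18)
  ## mixture mean is exact by construction
  mixMean <- sd0$w * (1 + sd0$smallMax) / 2 + (1 - sd0$w) * sd0$tailMean
  expect_equal(mixMean, 18, tolerance = 1e-9)
  ## CDF brackets the median
  F <- function(k) sd0$w * min(1, k / sd0$smallMax) +
    (1 - sd0$w) * (1 - (1 - sd0$tailP)^k)
  expect_lt(F(3), 0.5)
  expect_gte(F(4), 0.5)
  ## sample order statistics at scale
  set.seed(303)
  x <- sampleClusterSizes(2000, sd0)
  expect_true(median(x) >= 3 && median(x) <= 6)
  expect_true(mean(x) >= 15 && mean(x) <= 21)
})

test_that("zero density gives an empty scene; over-density errors", {
  sc <- buildScene(simConfig(clusterDensity = 0, seed = 1))
  expect_equal(nrow(sc@channels), 0L)
  expect_equal(trueMetrics(sc)$nClusters, 0L)
  expect_error(buildScene(simConfig(fieldSize = c(1500, 1500),
                                    clusterDensity = 400, seed = 1)),
               "placement failed")
})

test_that("cluster patches respect the footprint area bound", {
  ## an 18-channel patch at 30 nm footprint occupies >= 18 * 900 nm^2
  set.seed(5)
  p18 <- ryrclust:::makePatch(18, footprint = 30, occupancy = 1)
  bb <- (diff(range(p18[, 1])) + 30) * (diff(range(p18[, 2])) + 30)
  expect_gte(bb, 18 * 900 - 1e-6)
  expect_gte(min(dist(p18)), 30 - 1e-9)
  ## and the property holds for every cluster of a default scene
  sc <- buildScene(simConfig(fieldSize = c(4000, 4000), seed = 5))
  for (i in seq_len(trueMetrics(sc)$nClusters)) {
    ch <- sc@channels[sc@channelCluster == i, , drop = FALSE]
    n <- nrow(ch)
    bb <- (diff(range(ch[, 1])) + 30) * (diff(range(ch[, 2])) + 30)
    expect_gte(bb, n * 900 - 1e-6)
    if (n > 1) expect_gte(min(dist(ch)), 30 - 1e-9)
  }
  ## unmatchable order-statistic targets are refused clearly
  expect_error(solveSizeDist(median = 17, mean = 18, smallMax = 18),
               "cannot be matched")
})

test_that("stored true metrics equal brute-force recomputation exactly", {
  cfg <- simConfig(fieldSize = c(4000, 4000), seed = 21)
  sc <- buildScene(cfg)
  tm <- trueMetrics(sc)
  k <- tm$nClusters
  coords <- lapply(seq_len(k), function(i)
    sc@channels[sc@channelCluster == i, , drop = FALSE])
  ## exhaustive pairwise edge distances, no pruning
  nnd <- rep(Inf, k)
  edges <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- Inf
    for (t in seq_len(nrow(coords[[i]])))
      d <- min(d, sqrt((coords[[i]][t, 1] - coords[[j]][, 1])^2 +
                       (coords[[i]][t, 2] - coords[[j]][, 2])^2))
    d <- max(0, d - 30)
    nnd[i] <- min(nnd[i], d); nnd[j] <- min(nnd[j], d)
    if (d <= 150) edges <- rbind(edges, c(i, j))
  }
  expect_equal(tm$nnd, nnd)
  expect_equal(tm$pctWithinCutoff, 100 * mean(nnd <= 150))
  expect_equal(tm$meanClusterSize,
               mean(vapply(coords, nrow, integer(1))))
  expect_equal(tm$clusterDensity, k / 16)
  ## super-cluster membership matches an independent union-find
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(k), find, integer(1))
  expect_true(samePartition(sc@clusterSuper, roots))
  expect_equal(tm$clustersPerSupercluster, k / length(unique(roots)))
})

test_that("scenes and event tables are bit-for-bit reproducible", {
  cfg <- simConfig(fieldSize = c(3000, 3000), seed = 77)
  a <- buildScene(cfg); b <- buildScene(cfg)
  expect_identical(a@channels, b@channels)
  expect_identical(a@clusterSuper, b@clusterSuper)
  expect_identical(events(simulateEvents(a)), events(simulateEvents(b)))
  ## a different seed moves the geometry
  c2 <- buildScene(simConfig(fieldSize = c(3000, 3000), seed = 78))
  expect_false(identical(a@channels, c2@channels))
})

test_that("event simulation honours its closed-form mean and edge cases", {
  cfg0 <- simConfig(fieldSize = c(3000, 3000), labelingEfficiency = 0,
                    backgroundRate = 0, seed = 3)
  sc0 <- buildScene(cfg0)
  expect_equal(nrow(events(simulateEvents(sc0))), 0L)

  ## noiseless identity: sigma 0, one blink, full efficiency
  cfgN <- simConfig(fieldSize = c(3000, 3000), localizationSigma = 0,
                    blinksPerLabel = 1, labelingEfficiency = 1,
                    backgroundRate = 0, seed = 4)
  scN <- buildScene(cfgN)
  evN <- events(simulateEvents(scN))
  expect_equal(sort(evN$x_nm), sort(scN@channels[, 1]))
  expect_equal(nrow(evN), nrow(scN@channels))
  expect_true(all(evN$frame >= 0 & evN$frame < cfgN@nFrames))

  ## mean event count ~ efficiency * channels * blinks over many seeds
  base <- buildScene(simConfig(fieldSize = c(2000, 2000),
                               clusterDensity = 4, sizeMedian = 4,
                               sizeMean = 25, backgroundRate = 0, seed = 9))
  nCh <- nrow(base@channels)
  counts <- vapply(1:200, function(s) {
    cfg <- base@config
    cfg@seed <- as.integer(1000 + s)
    nrow(events(simulateEvents(base, cfg)))
  }, numeric(1))
  expected <- 0.5 * nCh * 5
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("widefield channel renders bands as ridges at the right spots", {
  cfg <- simConfig(fieldSize = c(3000, 3000), seed = 12)
  sc <- buildScene(cfg)
  ## no bands -> all-zero image
  sc0 <- sc; sc0@zdiskBands <- data.frame(center = numeric(0),
                                          width = numeric(0))
  img0 <- simulateActininWidefield(sc0)
  expect_true(all(pixelMatrix(img0) == 0))
  ## two bands 1800 nm apart -> profile peaks separated by 1800 +/- 1 px
  sc2 <- sc; sc2@zdiskBands <- data.frame(center = c(600, 2400),
                                          width = c(200, 200))
  img2 <- simulateActininWidefield(sc2, psfSigma = 250, pixelSize = 100)
  prof <- rowMeans(pixelMatrix(img2))
  pk <- order(prof, decreasing = TRUE)
  top2 <- sort(c(pk[1], pk[which(abs(pk - pk[1]) > 5)[1]]))
  expect_lte(abs(diff(top2) * 100 - 1800), 100)
  ## single band: symmetric around the center-line
  sc1 <- sc; sc1@zdiskBands <- data.frame(center = 1500, width = 200)
  p1 <- rowMeans(pixelMatrix(simulateActininWidefield(sc1, pixelSize = 100)))
  expect_equal(which.max(p1), 15, tolerance = 1)
})

test_that("scene and config serialization round-trips", {
  cfg <- simConfig(fieldSize = c(2000, 2000), seed = 6)
  tmp <- tempfile(fileext = ".yaml")
  writeSimConfigYaml(cfg, tmp)
  cfg2 <- readSimConfigYaml(tmp)
  expect_equal(configToList(cfg), configToList(cfg2))
  ## reloaded config regenerates the identical scene
  expect_identical(buildScene(cfg)@channels, buildScene(cfg2)@channels)
  sc <- buildScene(cfg)
  js <- tempfile(fileext = ".json")
  writeSceneJson(sc, js)
  expect_true(file.exists(js))
  expect_true(file.exists(sub("\\.json$", "_channels.csv", js)))
  ch <- read.csv(sub("\\.json$", "_channels.csv", js))
  expect_equal(nrow(ch), nrow(sc@channels))
})
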