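## image wrapper for hand-built intensity matrices
imgOf <- function(m, px = 5) new("RenderedImage", pixels = m, pixelSize = px,
                                 intensityScale = NA_real_, quantized = FALSE)

test_that("8-connected labeling matches an independent flood fill", {
  set.seed(101)
  for (rep in 1:20) {
    mask <- randomBlobMask(n = 80, k = 6, rRange = c(1, 6))
    a <- ryrclust:::label8(mask)
    b <- oracleLabel8(mask)
    expect_equal(max(a), max(b))
    expect_true(samePartition(a[mask], b[mask]))
  }
  ## diagonal touching is one cluster
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(max(ryrclust:::label8(m == 1)), 1L)
})

test_that("segmentation finds disjoint squares with exact pixel counts", {
  m <- matrix(0, 40, 40)
  m[5:10, 5:10] <- 1       # 36 px
  m[25:30, 20:28] <- 1     # 54 px
  set <- segmentClusters(imgOf(m), threshold = 0.5, minEvents = 0)
  cl <- clusters(set)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$n_pixels, c(36L, 54L))
  expect_equal(cl$area_nm2, cl$n_pixels * 25)
  expect_equal(cl$mean_intensity, cl$integrated_intensity / cl$n_pixels)
  ## all-zero image -> no clusters, empty set is not an error
  s0 <- segmentClusters(imgOf(matrix(0, 10, 10)), threshold = 0.5,
                        minEvents = 0)
  expect_equal(nClusters(s0), 0L)
})

test_that("min-events filter and border flags behave", {
  m <- matrix(0, 30, 30)
  m[1, 1:4] <- 1           # border-touching, mass 4
  m[10:12, 10:12] <- 2     # interior, mass 18
  m[20, 20] <- 0.5         # sub-threshold after masking? no: mass 0.5
  set <- segmentClusters(imgOf(m), threshold = 0.4, minEvents = 1)
  cl <- clusters(set)
  expect_equal(nrow(cl), 2L)   # the 0.5-mass singleton is dropped
  expect_equal(sort(cl$touches_border), c(FALSE, TRUE))
})

test_that("segmentation is idempotent on its own produced mask", {
  set.seed(202)
  mask <- randomBlobMask(n = 120, k = 10, rRange = c(2, 6))
  s1 <- segmentClusters(imgOf(mask * 1), threshold = 0.5, minEvents = 0)
  m2 <- (labelMatrix(s1) > 0) * 1
  s2 <- segmentClusters(imgOf(m2), threshold = 0.5, minEvents = 0)
  expect_equal(nClusters(s2), nClusters(s1))
  expect_equal(sort(clusters(s2)$n_pixels), sort(clusters(s1)$n_pixels))
  expect_true(samePartition(labelMatrix(s1)[labelMatrix(s1) > 0],
                            labelMatrix(s2)[labelMatrix(s2) > 0]))
})

test_that("channel-count estimation follows the footprint arithmetic", {
  expect_equal(estimateChannels(16200, 900), 18L)
  expect_equal(estimateChannels(450, 900), 1L)     # floor at one channel
  expect_equal(estimateChannels(0, 900), 1L)
  ## monotone non-decreasing in area
  a <- sort(runif(50, 0, 5e4))
  expect_true(all(diff(estimateChannels(a)) >= 0))
  expect_error(estimateChannels(900, footprint = 0), "footprint")
})

test_that("cluster density is count over analysis area", {
  m <- matrix(0, 40, 40)
  m[5:10, 5:10] <- 1
  roi <- matrix(1, 40, 40)
  set <- segmentClusters(imgOf(m), 0.5, minEvents = 0, roi = roi)
  ## 40 x 40 px at 5 nm = 0.04 um^2
  expect_equal(set@analysisArea, 0.04)
  expect_equal(clusterDensity(set), 1 / 0.04)
  s0 <- segmentClusters(imgOf(matrix(0, 10, 10)), 0.5, minEvents = 0)
  expect_error(clusterDensity(s0), "ROI")
})

test_that("nearest-neighbour distances reproduce simple geometry", {
  ## two single-pixel clusters 30 px apart at 5 nm/px -> 150 nm
  m <- matrix(0, 50, 50)
  m[10, 10] <- 1; m[10, 40] <- 1
  set <- nearestNeighborDistances(
    segmentClusters(imgOf(m), 0.5, minEvents = 0))
  expect_equal(clusters(set)$nnd_edge_nm, c(150, 150), tolerance = 2.5 / 150)
  ## one background pixel between two blocks -> 5 nm (one pixel)
  m2 <- matrix(0, 20, 20)
  m2[5:8, 5:8] <- 1; m2[5:8, 10:12] <- 1
  set2 <- nearestNeighborDistances(
    segmentClusters(imgOf(m2), 0.5, minEvents = 0))
  expect_equal(clusters(set2)$nnd_edge_nm, c(10, 10))
  ## fewer than two clusters warns and leaves NA
  m3 <- matrix(0, 10, 10); m3[4:6, 4:6] <- 1
  expect_warning(s3 <- nearestNeighborDistances(
    segmentClusters(imgOf(m3), 0.5, minEvents = 0)), "fewer than two")
  expect_true(all(is.na(clusters(s3)$nnd_edge_nm)))
})

test_that("pipeline NND equals the brute-force boundary-pair oracle", {
  set.seed(404)
  for (rep in 1:15) {
    mask <- randomBlobMask(n = 150, k = sample(3:9, 1))
    set <- segmentClusters(imgOf(mask * 1), 0.5, minEvents = 0)
    if (nClusters(set) < 2) next
    set <- nearestNeighborDistances(set)
    oracle <- oracleNndPixels(labelMatrix(set)) * 5
    expect_equal(clusters(set)$nnd_edge_nm, oracle, tolerance = 1e-9)
  }
})

test_that("the minimal NND is shared by a mutual pair", {
  set.seed(505)
  mask <- randomBlobMask(n = 200, k = 8)
  set <- suppressWarnings(nearestNeighborDistances(
    segmentClusters(imgOf(mask * 1), 0.5, minEvents = 0)))
  nnd <- clusters(set)$nnd_edge_nm
  if (length(nnd) >= 2)
    expect_gte(sum(abs(nnd - min(nnd)) < 1e-9), 2)
})

test_that("channel counts and mean NND recover simulated ground truth", {
  devs <- sizeDevs <- c()
  for (s in 1:5) {
    cfg <- simConfig(fieldSize = c(5000, 5000), labelingEfficiency = 1,
                     seed = 600 + s)
    sc <- buildScene(cfg); tm <- trueMetrics(sc)
    res <- analyzeImage(simulateEvents(sc))
    cl <- clusters(res$set)
    sizeDevs <- c(sizeDevs, mean(cl$est_channels) / tm$meanClusterSize)
    devs <- c(devs, mean(cl$nnd_edge_nm[!cl$touches_border], na.rm = TRUE) /
                mean(tm$nnd[is.finite(tm$nnd)]))
  }
  expect_lt(abs(mean(sizeDevs) - 1), 0.20)  # est channels within 20%
  expect_lt(abs(mean(devs) - 1), 0.10)      # mean NND within 10%
})
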