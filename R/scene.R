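## Scene construction ----------------------------------------------------
##
## Clusters are rectangular patches of channels on a square grid of pitch
## equal to the channel footprint, randomly rotated, thinned by the
## occupancy parameter. Super-cluster structure is built in directly:
## group sizes are drawn so that the configured fraction of clusters has an
## in-group neighbour at an edge gap below the grouping cutoff, members are
## chained at gaps drawn from gapRange, and distinct groups are kept at
## least interGroupSep apart edge-to-edge. All stored scene metrics are then
## recomputed from the final geometry by brute force, so construction
## approximations can never leak into the ground truth.

## union-find with path compression
ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

ufComponents <- function(n, edges) {
  parent <- seq_len(n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- ufFind(parent, edges[k, 1]); b <- ufFind(parent, edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
  match(roots, unique(roots))
}

## compact grid patch of n channel sites, random orientation, centred at 0
makePatch <- function(n, footprint, occupancy) {
  nsites <- ceiling(n / occupancy)
  aspect <- runif(1, 1, 2)
  ncol <- max(1L, ceiling(sqrt(nsites * aspect)))
  nrow <- ceiling(nsites / ncol)
  gx <- rep(seq_len(ncol), times = nrow)
  gy <- rep(seq_len(nrow), each = ncol)
  pts <- cbind((gx - (ncol + 1) / 2) * footprint,
               (gy - (nrow + 1) / 2) * footprint)
  ## keep the nsites grid sites closest to the centre, then thin to n
  ord <- order(pts[, 1]^2 + pts[, 2]^2)
  pts <- pts[ord[seq_len(min(nsites, nrow(pts)))], , drop = FALSE]
  if (nrow(pts) > n) pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
  th <- runif(1, 0, pi)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts %*% rot
}

## true edge-to-edge distance between two clusters: minimal channel
## centre-to-centre distance minus one footprint, floored at zero
trueEdgeDist <- function(a, b, footprint) {
  max(0, minPairDist(a, b) - footprint)
}

## all-pairs nearest-neighbour edge distances + adjacency at a cutoff,
## pruned by centroid-distance lower bounds but exact
clusterGeometryGraph <- function(coords, footprint, cutoff) {
  k <- length(coords)
  cent <- t(vapply(coords, colMeans, numeric(2)))
  rad <- vapply(seq_len(k), function(i) {
    sqrt(max(rowSums((coords[[i]] - rep(cent[i, ], each = nrow(coords[[i]])))^2)))
  }, numeric(1)) + footprint / 2
  nnd <- rep(Inf, k)
  edges <- matrix(integer(0), ncol = 2)
  if (k < 2) return(list(nnd = nnd, edges = edges))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      lb <- sqrt(sum((cent[i, ] - cent[j, ])^2)) - rad[i] - rad[j]
      if (lb > nnd[i] && lb > nnd[j] && lb > cutoff) next
      d <- trueEdgeDist(coords[[i]], coords[[j]], footprint)
      if (d < nnd[i]) nnd[i] <- d
      if (d < nnd[j]) nnd[j] <- d
      if (d <= cutoff) edges <- rbind(edges, c(i, j))
    }
  }
  list(nnd = nnd, edges = edges)
}

## brute-force scene metrics from final geometry; the stored ground truth
computeTrueMetrics <- function(coords, bands, config) {
  k <- length(coords)
  areaUm2 <- prod(config@fieldSize) / 1e6
  if (k == 0L) {
    return(list(nChannels = 0L, nClusters = 0L,
                clusterSizes = integer(0),
                meanClusterSize = NA_real_,
                clusterDensity = 0,
                nnd = numeric(0), pctWithinCutoff = NA_real_,
                clustersPerSupercluster = NA_real_,
                membership = integer(0),
                pctZdiskAligned = NA_real_,
                bandAreaFraction = bandAreaFraction(bands, config@fieldSize)))
  }
  geom <- clusterGeometryGraph(coords, config@channelFootprint,
                               config@superclusterGap)
  member <- ufComponents(k, geom$edges)
  sizes <- vapply(coords, nrow, integer(1))
  cent <- t(vapply(coords, colMeans, numeric(2)))
  aligned <- inBands(cent[, 2], bands)
  list(nChannels = sum(sizes), nClusters = k,
       clusterSizes = sizes,
       meanClusterSize = mean(sizes),
       clusterDensity = k / areaUm2,
       nnd = geom$nnd,
       pctWithinCutoff = 100 * mean(geom$nnd <= config@superclusterGap),
       clustersPerSupercluster = k / max(member),
       membership = as.integer(member),
       pctZdiskAligned = 100 * mean(aligned),
       bandAreaFraction = bandAreaFraction(bands, config@fieldSize))
}

inBands <- function(y, bands) {
  if (!nrow(bands)) return(rep(FALSE, length(y)))
  out <- rep(FALSE, length(y))
  for (b in seq_len(nrow(bands)))
    out <- out | abs(y - bands$center[b]) <= bands$width[b] / 2
  out
}

bandAreaFraction <- function(bands, fieldSize) {
  if (!nrow(bands)) return(0)
  ## bands are horizontal and non-overlapping at default geometry
  covered <- sum(pmin(bands$center + bands$width / 2, fieldSize[2]) -
                 pmax(bands$center - bands$width / 2, 0))
  covered / fieldSize[2]
}

## directional half-extent of a channel patch along unit vector u
dirExtent <- function(offsets, u) {
  max(offsets %*% u)
}

#' Build a ground-truth scene
#'
#' Places channel clusters in the field according to a
#' [SimulationConfig-class]: cluster count is Poisson at the configured
#' density, sizes follow the solved heavy-tailed mixture, a configured
#' fraction of super-clusters is seeded on z-disk bands, and in-group
#' members are chained at sub-cutoff edge gaps while distinct groups stay
#' separated. All stored scene metrics (`trueMetrics()`) are computed from
#' the final positions by brute force.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruthScene-class].
#' @seealso [simulateEvents()], [simulateActininWidefield()]
#' @examples
#' sc <- buildScene(simConfig(fieldSize = c(3000, 3000), seed = 3))
#' trueMetrics(sc)$meanClusterSize
#' @export
buildScene <- function(config) {
  validObject(config)
  withLocalSeed(splitSeed(config@seed, 1L), buildSceneImpl(config))
}

buildSceneImpl <- function(config) {
  fx <- config@fieldSize[1]; fy <- config@fieldSize[2]
  areaUm2 <- fx * fy / 1e6
  fp <- config@channelFootprint

  ## z-disk bands (fixed phase offset per scene)
  if (config@zdiskSpacing > 0 && config@zdiskWidth > 0 && fy >= config@zdiskWidth) {
    off <- runif(1, 0, config@zdiskSpacing)
    centers <- seq(off, fy, by = config@zdiskSpacing)
    ## only whole bands: a band clipped by the field edge is not a z-disk
    centers <- centers[centers >= config@zdiskWidth / 2 &
                       centers <= fy - config@zdiskWidth / 2]
    bands <- data.frame(center = centers,
                        width = rep(config@zdiskWidth, length(centers)))
  } else bands <- data.frame(center = numeric(0), width = numeric(0))

  nClusters <- rpois(1, config@clusterDensity * areaUm2)
  if (nClusters == 0L) {
    return(new("GroundTruthScene",
               channels = matrix(numeric(0), 0, 2),
               channelCluster = integer(0), clusterSuper = integer(0),
               zdiskBands = bands, fieldSize = config@fieldSize,
               trueMetrics = computeTrueMetrics(list(), bands, config),
               config = config))
  }

  ## group sizes hitting the within-fraction / mean-members targets:
  ## P(singleton) = (1 - f) * mu; multi-member sizes 2 + Geom
  p1 <- (1 - config@withinFraction) * config@meanMembers
  multiMean <- if (p1 < 1) config@withinFraction * config@meanMembers / (1 - p1) else 2
  multiMean <- max(2.000001, multiMean)
  groupSizes <- integer(0)
  while (sum(groupSizes) < nClusters) {
    gs <- if (runif(1) < p1) 1L else 2L + rgeom(1, prob = 1 / (multiMean - 1))
    groupSizes <- c(groupSizes, gs)
  }
  excess <- sum(groupSizes) - nClusters
  if (excess > 0)
    groupSizes[length(groupSizes)] <- groupSizes[length(groupSizes)] - excess
  groupSizes <- groupSizes[groupSizes > 0L]

  sizes <- sampleClusterSizes(nClusters, config@sizeDist)
  patches <- lapply(sizes, makePatch, footprint = fp,
                    occupancy = config@occupancy)
  radii <- vapply(patches, function(p) sqrt(max(rowSums(p^2))) + fp / 2,
                  numeric(1))

  coords <- vector("list", nClusters)   # placed channel coordinates
  cent <- matrix(NA_real_, nClusters, 2)
  groupOf <- integer(nClusters)
  placed <- 0L

  sampleSeedY <- function(ext, wantAligned) {
    lo <- ext; hi <- fy - ext
    if (hi <= lo) return(fy / 2)
    if (is.na(wantAligned)) return(runif(1, lo, hi))
    if (wantAligned) {
      b <- bands[sample.int(nrow(bands), 1), ]
      min(max(b$center + runif(1, -b$width / 2, b$width / 2), lo), hi)
    } else {
      for (t in seq_len(400)) {
        y <- runif(1, lo, hi)
        if (!inBands(y, bands)) return(y)
      }
      runif(1, lo, hi)
    }
  }

  ## exact edge-gap check of a candidate against placed clusters
  conflict <- function(cand, candCent, candRad, ids, minGapSame, groupIds) {
    for (j in ids) {
      lb <- sqrt(sum((candCent - cent[j, ])^2)) - candRad - radii[j]
      need <- if (j %in% groupIds) minGapSame else config@interGroupSep
      if (lb >= need) next
      d <- trueEdgeDist(cand, coords[[j]], fp)
      if (d < need) return(TRUE)
    }
    FALSE
  }

  za <- config@zdiskAlignedFraction
  ## contiguous cluster-index blocks per group; groups holding a giant
  ## cluster are placed first so large patches claim space while it
  ## exists (placement order does not enter any scene statistic), the
  ## rest keep their drawn order
  queue <- split(seq_len(nClusters), rep(seq_along(groupSizes), groupSizes))
  maxRad <- vapply(queue, function(ii) max(radii[ii]), numeric(1))
  big <- maxRad > 300
  queue <- c(queue[big][order(maxRad[big], decreasing = TRUE)], queue[!big])
  placedMask <- logical(nClusters)
  gidx <- 0L
  while (length(queue)) {
    members <- queue[[1]]
    gsz <- length(members)
    queue <- queue[-1]
    gidx <- gidx + 1L
    g <- gidx
    ok <- FALSE
    ## aligned groups string their members out along the band (the
    ## calcium-release-unit geometry along a z-disk); others chain
    ## isotropically. The decision is drawn once per group so crowded
    ## bands cannot silently convert aligned groups to interior ones;
    ## only after many failed attempts does the seed fall back to
    ## unconstrained placement.
    alignedGroup <- if (is.na(za) || !nrow(bands)) NA else runif(1) < za
    for (gtry in seq_len(60)) {
      ids <- integer(0)      # member cluster indices placed this attempt
      failed <- FALSE
      if (gtry > 15 && isTRUE(alignedGroup)) alignedGroup <- FALSE
      for (m in seq_len(gsz)) {
        ci <- members[m]
        patch <- patches[[ci]]
        ext <- radii[ci]
        placedIds <- which(placedMask)
        good <- FALSE
        for (mtry in seq_len(if (m == 1L) 400L else 120L)) {
          if (m == 1L) {
            cx <- runif(1, min(ext, fx / 2), max(fx - ext, fx / 2))
            cy <- sampleSeedY(ext, alignedGroup)
          } else {
            ## branch from any already-placed member (not just the chain
            ## end): keeps every member within the cutoff of an anchor
            ## while packing far more flexibly
            anchor <- ids[sample.int(m - 1L, 1L)]
            gap <- runif(1, config@gapRange[1], config@gapRange[2])
            th <- if (isTRUE(alignedGroup)) {
              ## stay along the band: direction within +/- 20 deg of the
              ## band axis, either way along it
              sample(c(0, pi), 1) + runif(1, -pi / 9, pi / 9)
            } else runif(1, 0, 2 * pi)
            u <- c(cos(th), sin(th))
            d0 <- dirExtent(coords[[anchor]] - rep(cent[anchor, ], each = nrow(coords[[anchor]])), u) +
              dirExtent(patch, -u) + gap + fp
            cx <- cent[anchor, 1] + d0 * u[1]
            cy <- cent[anchor, 2] + d0 * u[2]
          }
          if (m > 1L && isTRUE(alignedGroup) && !inBands(cy, bands) &&
              mtry < 40L)
            next  # members of a band group stay on their band
          cand <- patch + rep(c(cx, cy), each = nrow(patch))
          if (any(cand[, 1] < fp / 2 | cand[, 1] > fx - fp / 2 |
                  cand[, 2] < fp / 2 | cand[, 2] > fy - fp / 2)) next
          if (conflict(cand, c(cx, cy), ext, c(placedIds, ids), 10, ids)) next
          if (m > 1L) {
            dAnchor <- trueEdgeDist(cand, coords[[anchor]], fp)
            if (dAnchor > config@superclusterGap - 5 || dAnchor < 5) next
          }
          coords[[ci]] <- cand
          cent[ci, ] <- c(cx, cy)
          ids <- c(ids, ci)
          good <- TRUE
          break
        }
        if (!good) { failed <- TRUE; break }
      }
      if (!failed) { ok <- TRUE; break }
      coords[ids] <- list(NULL)  # discard partial group, retry
    }
    if (!ok) {
      if (gsz > 1L) {
        ## an unplaceable multi-member group is broken up and requeued:
        ## a CRU that cannot be chained in the remaining space becomes
        ## smaller CRUs rather than a hard failure
        half <- gsz %/% 2L
        queue <- c(queue, list(members[seq_len(half)]),
                   list(members[(half + 1L):gsz]))
        gidx <- gidx - 1L
        next
      }
      stop("cluster placement failed after bounded retries; ",
           "clusterDensity is too high for non-overlapping placement",
           call. = FALSE)
    }
    groupOf[members] <- g
    placedMask[members] <- TRUE
  }

  tm <- computeTrueMetrics(coords, bands, config)
  channels <- do.call(rbind, coords)
  channelCluster <- rep(seq_len(nClusters), times = vapply(coords, nrow, integer(1)))
  new("GroundTruthScene",
      channels = channels,
      channelCluster = as.integer(channelCluster),
      clusterSuper = as.integer(tm$membership),
      zdiskBands = bands,
      fieldSize = config@fieldSize,
      trueMetrics = tm,
      config = config)
}

#' Serialize a scene to JSON (+ CSV of channel positions)
#'
#' @param scene a [GroundTruthScene-class].
#' @param path JSON output path; a sibling `<path>_channels.csv` holds the
#'   channel table.
#' @return the JSON path, invisibly.
#' @export
writeSceneJson <- function(scene, path) {
  meta <- list(field_size_nm = scene@fieldSize,
               zdisk_bands = scene@zdiskBands,
               cluster_supercluster = scene@clusterSuper,
               true_metrics = scene@trueMetrics[
                 c("nChannels", "nClusters", "meanClusterSize",
                   "clusterDensity", "pctWithinCutoff",
                   "clustersPerSupercluster", "pctZdiskAligned",
                   "bandAreaFraction")],
               config = configToList(scene@config))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  csv <- sub("\\.json$", "", path)
  df <- data.frame(x_nm = scene@channels[, 1], y_nm = scene@channels[, 2],
                   cluster = scene@channelCluster)
  write.csv(df, paste0(csv, "_channels.csv"), row.names = FALSE)
  invisible(path)
}
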