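#' @title Core classes for nanoscale RyR2 cluster morphometry
#' @name ryrclust-classes
#' @description
#' S4 containers used across the pipeline: [SimulationConfig-class] holds the
#' generative parameters of a synthetic acquisition, [GroundTruthScene-class]
#' the true channel/cluster/super-cluster geometry, [EventTable-class] the
#' localization events, [RenderedImage-class] the density-proportional
#' rendered image, [ClusterSet-class] the segmented clusters and their
#' per-cluster morphometrics, [SuperClusterSet-class] the calcium-release-unit
#' grouping, and [ZDiskMask-class] the segmented z-disk reference channel.
NULL

#' Simulation parameters for a synthetic dSTORM acquisition
#'
#' Constructed with [simConfig()]; all lengths in nm, densities per square
#' micron. The cluster-size law is a two-component mixture (uniform small
#' component, geometric tail) whose weights are solved at construction time
#' to match the configured median and mean channel counts.
#'
#' @slot fieldSize numeric(2); field width and height in nm.
#' @slot channelFootprint numeric; edge length of one channel, nm.
#' @slot sizeDist list; solved cluster-size mixture (targets and parameters).
#' @slot clusterDensity numeric; clusters per square micron.
#' @slot occupancy numeric in (0, 1]; fraction of patch grid sites occupied.
#' @slot zdiskSpacing,zdiskWidth numeric; sarcomere band geometry, nm.
#' @slot zdiskAlignedFraction numeric in [0, 1], or NA for placement that
#'   ignores the bands entirely (uniform null geometry).
#' @slot withinFraction numeric; target fraction of clusters with a
#'   neighbour closer than the super-cluster cutoff.
#' @slot meanMembers numeric; target mean clusters per super-cluster.
#' @slot superclusterGap numeric; grouping cutoff the scene is built
#'   against, nm.
#' @slot gapRange numeric(2); edge-to-edge gap range for in-group
#'   neighbours, nm.
#' @slot interGroupSep numeric; minimum edge gap between distinct
#'   super-clusters, nm.
#' @slot labelingEfficiency numeric in [0, 1].
#' @slot blinksPerLabel numeric; mean of the geometric blink-count law.
#' @slot localizationSigma numeric; isotropic localization error, nm.
#' @slot backgroundRate numeric; background events per square micron.
#' @slot nFrames integer; frames in the simulated acquisition.
#' @slot seed integer; master seed, split per stage.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  fieldSize = "numeric",
  channelFootprint = "numeric",
  sizeDist = "list",
  clusterDensity = "numeric",
  occupancy = "numeric",
  zdiskSpacing = "numeric",
  zdiskWidth = "numeric",
  zdiskAlignedFraction = "numeric",
  withinFraction = "numeric",
  meanMembers = "numeric",
  superclusterGap = "numeric",
  gapRange = "numeric",
  interGroupSep = "numeric",
  labelingEfficiency = "numeric",
  blinksPerLabel = "numeric",
  localizationSigma = "numeric",
  backgroundRate = "numeric",
  nFrames = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive lengths (nm)")
  if (object@channelFootprint <= 0)
    msg <- c(msg, "channelFootprint must be > 0")
  if (object@localizationSigma < 0)
    msg <- c(msg, "localizationSigma must be >= 0")
  frac <- c(labelingEfficiency = object@labelingEfficiency,
            withinFraction = object@withinFraction,
            occupancy = object@occupancy)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  za <- object@zdiskAlignedFraction
  if (!is.na(za) && (za < 0 || za > 1))
    msg <- c(msg, "zdiskAlignedFraction must lie in [0, 1] or be NA")
  if (object@clusterDensity < 0 || object@backgroundRate < 0 ||
      object@blinksPerLabel < 1)
    msg <- c(msg, "rates must be non-negative (blinksPerLabel >= 1)")
  if (object@occupancy <= 0)
    msg <- c(msg, "occupancy must be > 0")
  if (length(object@gapRange) != 2L || any(object@gapRange <= 0) ||
      object@gapRange[1] > object@gapRange[2] ||
      object@gapRange[2] >= object@superclusterGap)
    msg <- c(msg, "gapRange must be increasing, positive and below superclusterGap")
  if (object@interGroupSep <= object@superclusterGap)
    msg <- c(msg, "interGroupSep must exceed superclusterGap")
  if (object@meanMembers < 1)
    msg <- c(msg, "meanMembers must be >= 1")
  if ((1 - object@withinFraction) * object@meanMembers > 1)
    msg <- c(msg, "withinFraction/meanMembers jointly infeasible (implied singleton probability > 1)")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground-truth geometry of a simulated scene
#'
#' Built by [buildScene()]. True per-scene metrics are computed by brute
#' force from the stored channel positions and are recomputable exactly;
#' they are the oracle every downstream measurement is compared against.
#'
#' @slot channels numeric matrix (n x 2), channel centers in nm.
#' @slot channelCluster integer; cluster id of each channel.
#' @slot clusterSuper integer; super-cluster id of each cluster.
#' @slot zdiskBands data.frame with columns `center`, `width` (nm); band
#'   center-lines run parallel to the x axis.
#' @slot fieldSize numeric(2), nm.
#' @slot trueMetrics list of brute-force scene metrics (see [trueMetrics()]).
#' @slot config the generating [SimulationConfig-class].
#' @exportClass GroundTruthScene
setClass("GroundTruthScene", representation(
  channels = "matrix",
  channelCluster = "integer",
  clusterSuper = "integer",
  zdiskBands = "data.frame",
  fieldSize = "numeric",
  trueMetrics = "list",
  config = "SimulationConfig"
))

setValidity("GroundTruthScene", function(object) {
  msg <- character()
  n <- nrow(object@channels)
  if (n > 0 && ncol(object@channels) != 2L)
    msg <- c(msg, "channels must be an n x 2 matrix")
  if (length(object@channelCluster) != n)
    msg <- c(msg, "one cluster id per channel required")
  nc <- if (n) max(object@channelCluster) else 0L
  if (n && !setequal(unique(object@channelCluster), seq_len(nc)))
    msg <- c(msg, "cluster ids must be 1..nClusters with no gaps")
  if (length(object@clusterSuper) != nc)
    msg <- c(msg, "one super-cluster id per cluster required")
  if (n && (any(object@channels[, 1] < 0 | object@channels[, 1] > object@fieldSize[1]) ||
            any(object@channels[, 2] < 0 | object@channels[, 2] > object@fieldSize[2])))
    msg <- c(msg, "channel positions must lie inside the field")
  if (length(msg)) msg else TRUE
})

#' Localization event table
#'
#' Rows are single-molecule events with positions in nm, a frame index in
#' `[0, nFrames)` and a photon-proportional weight (simulated events carry
#' unit weight). Created by [simulateEvents()] or read with [readEventsCsv()].
#'
#' @slot events data.frame with columns `x_nm`, `y_nm`, `frame`, `weight`.
#' @slot fieldSize numeric(2), nm; events are guaranteed inside the field.
#' @slot source character, `"simulated"` or `"file"`.
#' @exportClass EventTable
setClass("EventTable", representation(
  events = "data.frame",
  fieldSize = "numeric",
  source = "character"
))

setValidity("EventTable", function(object) {
  msg <- character()
  need <- c("x_nm", "y_nm", "frame", "weight")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, sprintf("events must have columns %s", paste(need, collapse = ", ")))
  else {
    ev <- object@events
    if (nrow(ev)) {
      if (any(ev$x_nm < 0 | ev$x_nm > object@fieldSize[1] |
              ev$y_nm < 0 | ev$y_nm > object@fieldSize[2]))
        msg <- c(msg, "all events must lie inside the field bounds")
      if (any(ev$frame < 0)) msg <- c(msg, "frame indices must be >= 0")
      if (any(ev$weight < 0)) msg <- c(msg, "weights must be non-negative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Density-proportional rendered image
#'
#' A 2D intensity grid at a fixed nm/pixel scale. Pixel (0,0) sits at the
#' field corner; pixel i covers the half-open interval
#' `[i*pixelSize, (i+1)*pixelSize)`; x maps to columns and y to rows.
#' Images circulate in continuous density units (`quantized = FALSE`);
#' [quantizeImage()] applies the recorded linear 16-bit scale for TIFF
#' export and `intensityScale` converts quantized counts back to density.
#'
#' @slot pixels numeric matrix (rows = y, columns = x), non-negative.
#' @slot pixelSize numeric, nm per pixel.
#' @slot intensityScale numeric; quantized counts per density unit
#'   (NA while unquantized).
#' @slot quantized logical.
#' @exportClass RenderedImage
setClass("RenderedImage", representation(
  pixels = "matrix",
  pixelSize = "numeric",
  intensityScale = "numeric",
  quantized = "logical"
))

setValidity("RenderedImage", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (any(object@pixels < 0)) msg <- c(msg, "intensities must be non-negative")
  if (isTRUE(object@quantized) && any(object@pixels > 65535))
    msg <- c(msg, "quantized intensities must be <= 2^16 - 1")
  if (length(msg)) msg else TRUE
})

#' Segmented RyR2 clusters and their morphometrics
#'
#' Produced by [segmentClusters()]. One row of `clusters` per 8-connected
#' component above threshold: pixel count, area (nm^2), integrated and mean
#' rendered intensity (the latter is the packing-density proxy, a.u.),
#' estimated channel count, centroid (nm), a border-touching flag, and the
#' edge-to-edge nearest-neighbour distance once
#' [nearestNeighborDistances()] has been run.
#'
#' @slot clusters data.frame of per-cluster records.
#' @slot labels integer matrix; 0 = background, k = pixels of cluster k.
#' @slot pixelSize numeric, nm.
#' @slot analysisArea numeric; denominator for cluster density, square microns.
#' @slot threshold numeric; intensity threshold used (density units).
#' @exportClass ClusterSet
setClass("ClusterSet", representation(
  clusters = "data.frame",
  labels = "matrix",
  pixelSize = "numeric",
  analysisArea = "numeric",
  threshold = "numeric"
))

setValidity("ClusterSet", function(object) {
  msg <- character()
  k <- nrow(object@clusters)
  if (k > 0) {
    lab <- sort(unique(as.integer(object@labels[object@labels > 0])))
    if (!identical(lab, seq_len(k)))
      msg <- c(msg, "label image must contain exactly the cluster ids 1..k")
    px <- tabulate(object@labels[object@labels > 0], nbins = k)
    if (!isTRUE(all.equal(object@clusters$area_nm2,
                          px * object@pixelSize^2)))
      msg <- c(msg, "area must equal pixel count times pixelSize^2")
  }
  if (!is.na(object@analysisArea) && object@analysisArea <= 0)
    msg <- c(msg, "analysisArea must be > 0")
  if (length(msg)) msg else TRUE
})

#' Super-cluster (calcium release unit) grouping
#'
#' Produced by [groupSuperclusters()]: the partition of a [ClusterSet-class]
#' into groups whose members are chained by edge-to-edge distances at or
#' below the cutoff (default 150 nm).
#'
#' @slot membership integer; group id per cluster (1..nGroups).
#' @slot groups data.frame: group id, member count, edge-to-edge distance to
#'   the nearest other group (nm; NA when only one group exists).
#' @slot cutoff numeric, nm.
#' @exportClass SuperClusterSet
setClass("SuperClusterSet", representation(
  membership = "integer",
  groups = "data.frame",
  cutoff = "numeric"
))

setValidity("SuperClusterSet", function(object) {
  msg <- character()
  if (length(object@membership)) {
    g <- sort(unique(object@membership))
    if (!identical(g, seq_len(nrow(object@groups))))
      msg <- c(msg, "membership must partition clusters into groups 1..nGroups")
    cnt <- tabulate(object@membership, nbins = nrow(object@groups))
    if (!identical(as.integer(object@groups$n_members), as.integer(cnt)))
      msg <- c(msg, "group member counts inconsistent with membership")
  }
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be > 0")
  if (length(msg)) msg else TRUE
})

#' Segmented z-disk reference mask
#'
#' Produced by [segmentZdisks()] from a diffraction-limited alpha-actinin
#' image resampled to the dSTORM pixel grid. `distanceMap` holds, for every
#' pixel, the exact Euclidean distance in nm to the nearest mask pixel
#' (zero on the mask itself).
#'
#' @slot mask logical matrix at the RyR2 image's pixel grid.
#' @slot distanceMap numeric matrix, nm.
#' @slot pixelSize numeric, nm.
#' @slot policy character; segmentation policy that produced the mask.
#' @exportClass ZDiskMask
setClass("ZDiskMask", representation(
  mask = "matrix",
  distanceMap = "matrix",
  pixelSize = "numeric",
  policy = "character"
))

setValidity("ZDiskMask", function(object) {
  msg <- character()
  if (!identical(dim(object@mask), dim(object@distanceMap)))
    msg <- c(msg, "mask and distanceMap must share dimensions")
  if (any(object@distanceMap < 0)) msg <- c(msg, "distances must be non-negative")
  if (any(object@distanceMap[object@mask] != 0))
    msg <- c(msg, "distanceMap must be 0 exactly on mask pixels")
  if (length(msg)) msg else TRUE
})

#' One metric's group comparison
#'
#' Result of [compareGroups()]: group summaries (mean +/- SEM over
#' patients), the test selected by the normality/variance decision tree,
#' its statistic and p-value, post-hoc pairwise p-values, and the logged
#' decision path.
#'
#' @slot metric character.
#' @slot summary data.frame: group, n, mean, sem.
#' @slot test character; one of "one-way ANOVA", "Welch ANOVA",
#'   "Kruskal-Wallis".
#' @slot statistic,p numeric.
#' @slot posthoc data.frame of pairwise comparisons (adjusted p-values).
#' @slot path character; the logged gate decisions.
#' @exportClass GroupComparison
setClass("GroupComparison", representation(
  metric = "character",
  summary = "data.frame",
  test = "character",
  statistic = "numeric",
  p = "numeric",
  posthoc = "data.frame",
  path = "character"
))

setValidity("GroupComparison", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  TRUE
})
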