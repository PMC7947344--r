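## Cluster-size law ------------------------------------------------------
##
## RyR2 cluster sizes are strongly right-skewed: roughly half of the
## clusters carry fewer than ~4-5 channels while the mean sits near 18.
## No one-parameter counting law does both, so the generator uses a
## two-component mixture: with weight w a "small cluster" drawn uniformly
## from {1..smallMax}, otherwise a geometric tail on {1, 2, ...}. Given the
## target median M and mean mu, the weight w and tail mean are solved
## numerically so that the mixture mean equals mu exactly and the mixture
## CDF at M sits at 0.55 — comfortably past 0.5, pinning the distribution
## median at M while F(M - 1) stays below 0.5.

solveSizeDist <- function(median = 4, mean = 18, smallMax = 6) {
  stopifnot(median >= 1, mean > median, smallMax >= median)
  ms <- (1 + smallMax) / 2
  fsmall <- function(k) pmin(1, pmax(0, floor(k)) / smallMax)
  mixF <- function(k, w, m) w * fsmall(k) + (1 - w) * (1 - (1 - 1 / m)^floor(k))
  tailMean <- function(w) (mean - w * ms) / (1 - w)
  obj <- function(w) mixF(median, w, tailMean(w)) - 0.55
  hi <- min(0.995, (mean - 1 - 1e-9) / (ms - 1))  # keep tail mean > 1
  if (obj(1e-6) * obj(hi) > 0)
    stop("cluster-size targets (median ", median, ", mean ", mean,
         ") cannot be matched by the mixture law; widen the gap between ",
         "median and mean", call. = FALSE)
  sol <- uniroot(obj, lower = 1e-6, upper = hi, tol = 1e-12)
  w <- sol$root
  m <- tailMean(w)
  if (mixF(median - 1, w, m) >= 0.5)
    warning("size-distribution solve did not pin the median exactly")
  list(median = median, mean = mean, smallMax = smallMax,
       w = w, tailMean = m, tailP = 1 / m)
}

sampleClusterSizes <- function(n, sizeDist) {
  if (n == 0L) return(integer(0))
  small <- runif(n) < sizeDist$w
  out <- integer(n)
  out[small] <- sample.int(sizeDist$smallMax, sum(small), replace = TRUE)
  out[!small] <- rgeom(sum(!small), prob = sizeDist$tailP) + 1L
  out
}

#' Configure a synthetic dSTORM acquisition
#'
#' Builds and validates a [SimulationConfig-class]. Defaults emulate the
#' RyR2 organization reported for human right-atrial cardiomyocytes:
#' ~30 nm channel footprint, ~4.3 clusters per square micron with a
#' heavy-tailed size law (median ~4, mean ~18 channels), ~70% of clusters
#' within 150 nm of a neighbour and ~2.2 clusters per super-cluster,
#' quasi-periodic z-disk bands 1.8 um apart, and a ~20,000-frame blinking
#' acquisition localized with ~15 nm precision.
#'
#' @param fieldSize numeric(2); field extent in nm (default 6000 x 6000).
#' @param channelFootprint channel edge length, nm.
#' @param sizeMedian,sizeMean,sizeSmallMax targets for the cluster-size
#'   mixture (channels per cluster); the mixture parameters are solved here.
#' @param clusterDensity clusters per square micron.
#' @param occupancy fraction of grid sites inside a cluster patch that carry
#'   a channel.
#' @param zdiskSpacing,zdiskWidth z-disk band period and width, nm.
#' @param zdiskAlignedFraction fraction of super-clusters seeded on a band;
#'   the remainder are placed between bands. `NA` places all clusters
#'   uniformly, ignoring bands (the null geometry used for calibration).
#' @param withinFraction target fraction of clusters whose nearest
#'   neighbour lies within `superclusterGap`.
#' @param meanMembers target mean clusters per super-cluster.
#' @param superclusterGap grouping cutoff, nm.
#' @param gapRange numeric(2); in-group edge-to-edge gaps are drawn
#'   uniformly from this range (must sit below `superclusterGap`).
#' @param interGroupSep minimum edge gap enforced between distinct
#'   super-clusters, nm (must exceed `superclusterGap`).
#' @param labelingEfficiency probability a channel carries a detected label.
#' @param blinksPerLabel mean of the geometric blink-count distribution.
#' @param localizationSigma isotropic localization error, nm.
#' @param backgroundRate spurious events per square micron.
#' @param nFrames frames in the acquisition.
#' @param seed master seed; identical (config, seed) pairs reproduce scenes
#'   and event tables bit for bit.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simConfig(fieldSize = c(3000, 3000), seed = 7)
#' cfg
#' @export
simConfig <- function(fieldSize = c(6000, 6000),
                      channelFootprint = 30,
                      sizeMedian = 4, sizeMean = 18, sizeSmallMax = 6,
                      clusterDensity = 4.3,
                      occupancy = 1,
                      zdiskSpacing = 1800,
                      zdiskWidth = 200,
                      zdiskAlignedFraction = 0.45,
                      withinFraction = 0.70,
                      meanMembers = 2.18,
                      superclusterGap = 150,
                      gapRange = c(60, 140),
                      interGroupSep = 220,
                      labelingEfficiency = 0.5,
                      blinksPerLabel = 5,
                      localizationSigma = 15,
                      backgroundRate = 2,
                      nFrames = 20000,
                      seed = 1) {
  sizeDist <- solveSizeDist(sizeMedian, sizeMean, sizeSmallMax)
  new("SimulationConfig",
      fieldSize = as.numeric(fieldSize),
      channelFootprint = as.numeric(channelFootprint),
      sizeDist = sizeDist,
      clusterDensity = as.numeric(clusterDensity),
      occupancy = as.numeric(occupancy),
      zdiskSpacing = as.numeric(zdiskSpacing),
      zdiskWidth = as.numeric(zdiskWidth),
      zdiskAlignedFraction = as.numeric(zdiskAlignedFraction),
      withinFraction = as.numeric(withinFraction),
      meanMembers = as.numeric(meanMembers),
      superclusterGap = as.numeric(superclusterGap),
      gapRange = as.numeric(gapRange),
      interGroupSep = as.numeric(interGroupSep),
      labelingEfficiency = as.numeric(labelingEfficiency),
      blinksPerLabel = as.numeric(blinksPerLabel),
      localizationSigma = as.numeric(localizationSigma),
      backgroundRate = as.numeric(backgroundRate),
      nFrames = as.integer(nFrames),
      seed = as.integer(seed))
}

## flat named list <-> config, for YAML round trips
configToList <- function(config) {
  list(field_size_nm = config@fieldSize,
       channel_footprint_nm = config@channelFootprint,
       size_median = config@sizeDist$median,
       size_mean = config@sizeDist$mean,
       size_small_max = config@sizeDist$smallMax,
       cluster_density_per_um2 = config@clusterDensity,
       occupancy = config@occupancy,
       zdisk_spacing_nm = config@zdiskSpacing,
       zdisk_width_nm = config@zdiskWidth,
       zdisk_aligned_fraction = config@zdiskAlignedFraction,
       within_fraction = config@withinFraction,
       mean_members = config@meanMembers,
       supercluster_gap_nm = config@superclusterGap,
       gap_range_nm = config@gapRange,
       inter_group_sep_nm = config@interGroupSep,
       labeling_efficiency = config@labelingEfficiency,
       blinks_per_label = config@blinksPerLabel,
       localization_sigma_nm = config@localizationSigma,
       background_rate_per_um2 = config@backgroundRate,
       n_frames = config@nFrames,
       seed = config@seed)
}

listToConfig <- function(x) {
  simConfig(fieldSize = x$field_size_nm,
            channelFootprint = x$channel_footprint_nm,
            sizeMedian = x$size_median, sizeMean = x$size_mean,
            sizeSmallMax = x$size_small_max,
            clusterDensity = x$cluster_density_per_um2,
            occupancy = x$occupancy,
            zdiskSpacing = x$zdisk_spacing_nm,
            zdiskWidth = x$zdisk_width_nm,
            zdiskAlignedFraction = x$zdisk_aligned_fraction,
            withinFraction = x$within_fraction,
            meanMembers = x$mean_members,
            superclusterGap = x$supercluster_gap_nm,
            gapRange = x$gap_range_nm,
            interGroupSep = x$inter_group_sep_nm,
            labelingEfficiency = x$labeling_efficiency,
            blinksPerLabel = x$blinks_per_label,
            localizationSigma = x$localization_sigma_nm,
            backgroundRate = x$background_rate_per_um2,
            nFrames = x$n_frames,
            seed = x$seed)
}

#' Write or read a simulation config as YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path file path.
#' @return `readSimConfigYaml()` returns the reconstructed config;
#'   `writeSimConfigYaml()` its path, invisibly. The round trip is lossless.
#' @export
writeSimConfigYaml <- function(config, path) {
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

#' @rdname writeSimConfigYaml
#' @export
readSimConfigYaml <- function(path) {
  listToConfig(yaml::read_yaml(path))
}
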