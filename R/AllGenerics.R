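#' Accessors for ryrclust containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of one of the classes in [ryrclust-classes].
#' @return `clusters()` the per-cluster data.frame; `events()` the event
#'   data.frame; `pixelSize()` the nm/pixel scale; `pixelMatrix()` the raw
#'   intensity matrix; `labelMatrix()` the integer label image;
#'   `trueMetrics()` the brute-force scene metrics list; `membership()` the
#'   per-cluster super-cluster ids; `nClusters()` a count.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("trueMetrics", function(x) standardGeneric("trueMetrics"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
setMethod("events", "EventTable", function(x) x@events)
#' @rdname accessors
setMethod("pixelSize", "RenderedImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ClusterSet", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ZDiskMask", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelMatrix", "RenderedImage", function(x) x@pixels)
#' @rdname accessors
setMethod("labelMatrix", "ClusterSet", function(x) x@labels)
#' @rdname accessors
setMethod("trueMetrics", "GroundTruthScene", function(x) x@trueMetrics)
#' @rdname accessors
setMethod("membership", "SuperClusterSet", function(x) x@membership)
#' @rdname accessors
setMethod("nClusters", "ClusterSet", function(x) nrow(x@clusters))
#' @rdname accessors
setMethod("nClusters", "GroundTruthScene", function(x) length(x@clusterSuper))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%.0f x %.0f nm field,", object@fieldSize[1], object@fieldSize[2]),
      sprintf("%.2f clusters/um^2,", object@clusterDensity),
      sprintf("size law median %.3g / mean %.3g channels,",
              object@sizeDist$median, object@sizeDist$mean),
      sprintf("seed %d", object@seed), "\n")
})

setMethod("show", "GroundTruthScene", function(object) {
  tm <- object@trueMetrics
  cat(sprintf("GroundTruthScene: %d channels in %d clusters / %d super-clusters\n",
              nrow(object@channels), length(object@clusterSuper),
              if (length(object@clusterSuper)) max(object@clusterSuper) else 0L))
  if (length(tm))
    cat(sprintf("  true mean size %.2f channels, density %.2f /um^2, %.1f%% within %g nm\n",
                tm$meanClusterSize, tm$clusterDensity, tm$pctWithinCutoff,
                object@config@superclusterGap))
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events (%s), field %.0f x %.0f nm\n",
              nrow(object@events), object@source,
              object@fieldSize[1], object@fieldSize[2]))
})

setMethod("show", "RenderedImage", function(object) {
  cat(sprintf("RenderedImage: %d x %d px at %g nm/px (%s)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              if (object@quantized) "16-bit quantized" else "density units"))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters, analysis area %.2f um^2, threshold %.4g\n",
              nrow(object@clusters), object@analysisArea, object@threshold))
})

setMethod("show", "SuperClusterSet", function(object) {
  cat(sprintf("SuperClusterSet: %d clusters in %d groups (cutoff %g nm)\n",
              length(object@membership), nrow(object@groups), object@cutoff))
})

setMethod("show", "ZDiskMask", function(object) {
  cat(sprintf("ZDiskMask: %d x %d px, %.1f%% mask coverage (%s)\n",
              nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask), object@policy))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s]: %s, p = %.4g\n",
              object@metric, object@test, object@p))
  print(object@summary, row.names = FALSE)
})
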