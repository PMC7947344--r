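## Cluster segmentation and per-cluster morphometrics --------------------

## 8-connected labeling: EBImage::bwlabel (4-connected) plus a union-find
## merge of diagonally adjacent labels.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  edges <- matrix(integer(0), 0, 2)
  if (nr > 1L && nc > 1L) {
    a <- lab[-nr, -nc]; b <- lab[-1, -1]          # down-right diagonal
    s <- a > 0L & b > 0L & a != b
    if (any(s)) edges <- rbind(edges, cbind(a[s], b[s]))
    a <- lab[-1, -nc]; b <- lab[-nr, -1]          # up-right diagonal
    s <- a > 0L & b > 0L & a != b
    if (any(s)) edges <- rbind(edges, cbind(a[s], b[s]))
  }
  comp <- ufComponents(n, unique(edges))
  out <- lab
  out[lab > 0L] <- comp[lab[lab > 0L]]
  out
}

## relabel a label image so ids are 1..k in first-appearance order
relabelConsecutive <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (!length(ids)) return(lab)
  out <- lab
  out[lab > 0L] <- match(lab[lab > 0L], sort(ids))
  out
}

## analysis area (um^2): morphological closing of the labeling with a disc
## of the given radius, computed through two exact distance transforms
closingAreaUm2 <- function(mask, radiusNm, pixelSize) {
  r <- radiusNm / pixelSize
  if (!any(mask)) return(NA_real_)
  d1 <- EBImage::distmap(1 - mask)          # distance to nearest mask pixel
  dil <- d1 <= r
  d2 <- EBImage::distmap(dil)               # distance to nearest non-dilated
  closed <- d2 > r
  sum(closed) * pixelSize^2 / 1e6
}

#' Segment RyR2 clusters from a rendered image
#'
#' Thresholds the image (`pixels >= threshold`, intersected with `roi` if
#' given), labels 8-connected components, discards components whose
#' integrated intensity corresponds to fewer than `minEvents` localization
#' events, and computes per-cluster morphometrics: area, integrated and
#' mean intensity (packing density, a.u.), estimated channel count
#' (area-based by default, see [estimateChannels()]), centroid, and a flag
#' for components touching the image border. The analysis area used for
#' cluster density is the ROI area when an ROI is supplied, otherwise the
#' area of the morphological closing (radius `closingRadius`) of the
#' thresholded labeling — a proxy for the labeled cell footprint.
#'
#' @param image a [RenderedImage-class]; quantized images are converted to
#'   density units through their recorded scale.
#' @param threshold intensity threshold in density units (see
#'   [estimateThreshold()]).
#' @param minEvents minimum integrated event mass per retained component.
#' @param roi optional logical matrix (same dimensions) restricting the
#'   analysis.
#' @param footprint channel footprint area in nm^2 used for channel-count
#'   estimation (default 900 = 30 x 30 nm).
#' @param closingRadius radius (nm) of the closing used for the analysis
#'   area when no ROI is given.
#' @param refineFraction two-threshold delineation: after detection, each
#'   cluster's pixel set is re-cut at this fraction of its median
#'   intensity (largest connected piece kept), trimming the localization-
#'   blur rim so areas and edge distances track the true channel
#'   footprint. `NULL` or 0 keeps the raw detection mask.
#' @return a [ClusterSet-class]; empty mask gives an empty set.
#' @export
segmentClusters <- function(image, threshold, minEvents = 3, roi = NULL,
                            footprint = 900, closingRadius = 1000,
                            refineFraction = 0.55) {
  stopifnot(is(image, "RenderedImage"))
  assertScalar(threshold, "threshold", lo = 0, strict_lo = TRUE)
  img <- toDensity(image)
  px <- img@pixels
  psz <- img@pixelSize
  mask <- px >= threshold
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(px)))
    mask <- mask & (roi > 0)
  }
  lab <- label8(mask)
  k <- max(lab)
  emptySet <- function(area) new("ClusterSet",
    clusters = data.frame(id = integer(0), n_pixels = integer(0),
                          area_nm2 = numeric(0),
                          integrated_intensity = numeric(0),
                          mean_intensity = numeric(0),
                          est_channels = integer(0),
                          centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
                          touches_border = logical(0), nnd_edge_nm = numeric(0)),
    labels = lab, pixelSize = psz, analysisArea = area,
    threshold = threshold)
  analysisArea <- if (!is.null(roi)) sum(roi > 0) * psz^2 / 1e6
                  else closingAreaUm2(mask, closingRadius, psz)
  if (k == 0L) return(emptySet(analysisArea))

  ## per-component sums on the flattened label vector
  idx <- which(lab > 0L)
  ids <- lab[idx]
  wsum <- rowsum(px[idx], ids)
  npx <- tabulate(ids, nbins = k)
  keep <- which(wsum[, 1] >= minEvents)
  if (!length(keep)) {
    lab[] <- 0L
    return(emptySet(analysisArea))
  }
  lab[!(lab %in% keep)] <- 0L
  lab <- relabelConsecutive(lab)
  k <- max(lab)
  if (!is.null(refineFraction) && refineFraction > 0)
    lab <- refineClusterMask(lab, px, refineFraction)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  npx <- tabulate(ids, nbins = k)
  isum <- rowsum(px[idx], ids)[, 1]
  cx <- rowsum((cols - 0.5) * psz, ids)[, 1] / npx
  cy <- rowsum((rows - 0.5) * psz, ids)[, 1] / npx
  border <- rowsum(as.numeric(rows == 1L | rows == nrow(lab) |
                              cols == 1L | cols == ncol(lab)), ids)[, 1] > 0
  area <- npx * psz^2
  df <- data.frame(id = seq_len(k),
                   n_pixels = npx,
                   area_nm2 = area,
                   integrated_intensity = isum,
                   mean_intensity = isum / npx,
                   est_channels = estimateChannels(area, footprint),
                   centroid_x_nm = cx, centroid_y_nm = cy,
                   touches_border = border,
                   nnd_edge_nm = rep(NA_real_, k))
  new("ClusterSet", clusters = df, labels = lab, pixelSize = psz,
      analysisArea = analysisArea, threshold = threshold)
}

## two-threshold delineation: keep, per cluster, the largest connected
## piece of { pixels >= frac * median(cluster intensities) }. The rim that
## localization error and the rendering kernel add around the true channel
## area sits well below the in-cluster median, so this recovers the
## physical footprint while detection sensitivity stays with the low
## threshold.
refineClusterMask <- function(lab, px, frac) {
  nr <- nrow(lab)
  out <- matrix(0L, nr, ncol(lab))
  k <- max(lab)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  byId <- split(idx, factor(ids, levels = seq_len(k)))
  for (i in seq_len(k)) {
    pos <- byId[[i]]
    thr <- frac * median(px[pos])
    sel <- pos[px[pos] >= thr]
    if (!length(sel)) sel <- pos
    rows <- ((sel - 1L) %% nr) + 1L
    cols <- ((sel - 1L) %/% nr) + 1L
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    sl <- label8(sub)
    if (max(sl) > 1L) {
      big <- which.max(tabulate(sl[sl > 0L], nbins = max(sl)))
      keepPix <- sl[cbind(rows - r0 + 1L, cols - c0 + 1L)] == big
      sel <- sel[keepPix]
    }
    out[sel] <- i
  }
  out
}

#' Estimate channels per cluster from area
#'
#' Channel count is the cluster area divided by the single-channel
#' footprint (900 nm^2 for a ~30 x 30 nm channel), rounded, floored at one
#' channel: every retained cluster holds at least one channel.
#'
#' @param areaNm2 cluster area(s) in nm^2.
#' @param footprint single-channel footprint in nm^2.
#' @return integer channel count(s), monotone non-decreasing in area.
#' @export
estimateChannels <- function(areaNm2, footprint = 900) {
  assertScalar(footprint, "footprint", lo = 0, strict_lo = TRUE)
  as.integer(pmax(1, round(areaNm2 / footprint)))
}

#' Cluster density of a segmented set
#'
#' @param set a [ClusterSet-class].
#' @return clusters per square micron over the set's analysis area.
#' @export
clusterDensity <- function(set) {
  stopifnot(is(set, "ClusterSet"))
  if (is.na(set@analysisArea))
    stop("analysis area unavailable: supply an ROI or a non-empty mask",
         call. = FALSE)
  nrow(set@clusters) / set@analysisArea
}

## boundary pixels (any 4-neighbour missing) of each label, as pixel coords
boundaryPixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  inner <- core > 0L &
    pad[1:nr, 2:(nc + 1L)] == core & pad[3:(nr + 2L), 2:(nc + 1L)] == core &
    pad[2:(nr + 1L), 1:nc] == core & pad[2:(nr + 1L), 3:(nc + 2L)] == core
  bnd <- core > 0L & !inner
  idx <- which(bnd)
  data.frame(id = core[idx],
             row = ((idx - 1L) %% nr) + 1L,
             col = ((idx - 1L) %/% nr) + 1L)
}

## Per-label edge-to-edge nearest-neighbour distances (pixel units) on a
## label image: for each label, an exact Euclidean distance transform of
## the other labels is computed on a window around the label's bounding
## box, sampled at the label's own pixels; the window doubles until the
## minimum found is certified global.
nndOfLabels <- function(lab) {
  k <- max(lab)
  out <- rep(NA_real_, k)
  if (k < 2L) return(out)
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  f <- factor(ids, levels = seq_len(k))
  r0 <- tapply(rows, f, min); r1 <- tapply(rows, f, max)
  c0 <- tapply(cols, f, min); c1 <- tapply(cols, f, max)
  for (i in seq_len(k)) {
    R <- 64
    repeat {
      wr <- max(1, r0[i] - R):min(nr, r1[i] + R)
      wc <- max(1, c0[i] - R):min(nc, c1[i] + R)
      sub <- lab[wr, wc, drop = FALSE]
      others <- sub > 0L & sub != i
      full <- length(wr) == nr && length(wc) == nc
      if (any(others)) {
        D <- EBImage::distmap(matrix(as.numeric(!others), nrow(sub)))
        d <- min(D[sub == i])
        if (d <= R || full) { out[i] <- d; break }
      } else if (full) { out[i] <- Inf; break }
      R <- R * 2
    }
  }
  out
}

#' Edge-to-edge nearest-neighbour distances between clusters
#'
#' For each cluster, the minimal edge-to-edge Euclidean distance to any
#' other cluster, measured on the pixel grid: the exact distance transform
#' of the remaining clusters sampled at the focal cluster's pixels
#' (equivalently, the minimum over pixel-centre pairs). Border-touching
#' clusters keep their value but are flagged so summary statistics can
#' exclude them (their true neighbour may lie outside the field); they
#' remain usable as neighbours of interior clusters.
#'
#' @param set a [ClusterSet-class].
#' @return the set with `clusters$nnd_edge_nm` filled (nm). With fewer
#'   than two clusters a warning is raised and values stay `NA`.
#' @export
nearestNeighborDistances <- function(set) {
  stopifnot(is(set, "ClusterSet"))
  if (nrow(set@clusters) < 2L) {
    warning("fewer than two clusters: nearest-neighbour distances undefined")
    return(set)
  }
  set@clusters$nnd_edge_nm <- nndOfLabels(set@labels) * set@pixelSize
  set
}

#' Write a per-cluster CSV
#'
#' One row per [ClusterSet-class] record, with the documented column names
#' of the `clusters` accessor.
#'
#' @param set a [ClusterSet-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeClustersCsv <- function(set, path) {
  write.csv(clusters(set), path, row.names = FALSE)
  invisible(path)
}
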