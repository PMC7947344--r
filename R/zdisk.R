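## z-disk (alpha-actinin) reference-channel analysis ---------------------

## nearest-neighbour resampling of a widefield image onto a target grid
resampleToGrid <- function(image, pixelSize, dim) {
  src <- image@pixels
  rows <- pmin(nrow(src), pmax(1L, ceiling((seq_len(dim[1]) - 0.5) *
                                             pixelSize / image@pixelSize)))
  cols <- pmin(ncol(src), pmax(1L, ceiling((seq_len(dim[2]) - 0.5) *
                                             pixelSize / image@pixelSize)))
  src[rows, cols, drop = FALSE]
}

#' Segment z-disks from a widefield alpha-actinin image
#'
#' Resamples the diffraction-limited image to the dSTORM pixel grid and
#' produces a binary z-disk mask plus the exact Euclidean distance map (nm)
#' to the nearest mask pixel. Policies:
#' \describe{
#'   \item{`"ridge"` (default)}{treats the image as a set of roughly
#'     horizontal blurred bands: band center-lines are found as peaks of
#'     the row-mean intensity profile, the physical band width is
#'     estimated from the profile's local second moment after removing the
#'     PSF variance (a blurred top-hat of width w has variance
#'     psf^2 + w^2/12), and the mask covers `|y - center| <= w/2`. This
#'     undoes the optical blur, which is typically wider than the band
#'     itself and would otherwise inflate the mask several-fold.}
#'   \item{`"otsu"`}{Otsu threshold on the nonzero resampled intensities.}
#'   \item{`"quantile"`}{keeps the brightest `value`-fraction of pixels.}
#' }
#'
#' @param actinin a [RenderedImage-class] (widefield channel, registered to
#'   the dSTORM field; registration itself is out of scope and fields are
#'   assumed to share coordinates).
#' @param targetPixelSize nm/pixel of the dSTORM grid the mask must live on
#'   (default 5).
#' @param targetDim optional integer(2) rows/cols of the target grid;
#'   derived from the image extent when missing.
#' @param policy segmentation policy.
#' @param psfSigma assumed PSF scale (nm) for the ridge policy.
#' @param value fraction kept by the quantile policy.
#' @return a [ZDiskMask-class]; an all-zero channel is an error.
#' @export
segmentZdisks <- function(actinin, targetPixelSize = 5, targetDim = NULL,
                          policy = c("ridge", "otsu", "quantile"),
                          psfSigma = 250, value = 0.15) {
  stopifnot(is(actinin, "RenderedImage"))
  policy <- match.arg(policy)
  img <- toDensity(actinin)
  if (all(img@pixels == 0))
    stop("no z-disk signal: alpha-actinin channel is blank", call. = FALSE)
  if (is.null(targetDim)) {
    targetDim <- c(round(nrow(img@pixels) * img@pixelSize / targetPixelSize),
                   round(ncol(img@pixels) * img@pixelSize / targetPixelSize))
  }
  px <- resampleToGrid(img, targetPixelSize, targetDim)

  mask <- switch(policy,
    otsu = px >= otsuNonzero(px[px > 0]),
    quantile = px >= as.numeric(quantile(px[px > 0], 1 - value)),
    ridge = ridgeBandMask(px, targetPixelSize, psfSigma,
                          sourcePixelSize = img@pixelSize))
  if (!any(mask))
    stop("no z-disk signal: segmentation produced an empty mask", call. = FALSE)
  dm <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask))) * targetPixelSize
  new("ZDiskMask", mask = mask, distanceMap = dm,
      pixelSize = targetPixelSize, policy = policy)
}

## ridge policy: bands are contiguous above-half-max segments of the
## row-mean profile; each band's center is the segment's intensity
## centroid and its physical width comes from the local second moment with
## the PSF variance removed (blurred top-hat of width w: psf^2 + w^2/12)
ridgeBandMask <- function(px, pixelSize, psfSigma, sourcePixelSize = 0) {
  prof <- rowMeans(px)
  ny <- length(prof)
  above <- prof > 0.5 * max(prof)
  runs <- rle(above)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  segs <- cbind(starts[runs$values], stops[runs$values])
  y <- seq_len(ny)
  centers <- apply(segs, 1, function(s) {
    w <- prof[s[1]:s[2]]
    sum(w * (s[1]:s[2])) / sum(w)
  })
  mask <- matrix(FALSE, nrow(px), ncol(px))
  L <- 3.5 * psfSigma                      # moment window half-width, nm
  half <- max(1, round(L / pixelSize))
  ## width estimation needs the full symmetric window; bands too close to
  ## the field edge inherit the median width of the fully-windowed bands
  ## (z-disks across one cell share their width)
  bws <- rep(NA_real_, length(centers))
  for (b in seq_along(centers)) {
    cc <- centers[b]
    if (cc - half < 1 || cc + half > ny) next
    win <- y >= cc - half & y <= cc + half
    w <- prof[win]
    if (sum(w) <= 0) next
    yy <- (y[win] - cc) * pixelSize
    v <- sum(w * yy^2) / sum(w)            # truncated second moment, nm^2
    ## undo window truncation (Gaussian approximation, fixed point), then
    ## remove PSF variance and the source camera's pixel-integration
    ## variance; a blurred top-hat of width bw carries bw^2/12 of its own
    sigma2 <- v
    for (it in 1:4) {
      a <- L / sqrt(sigma2)
      shrink <- 1 - 2 * a * dnorm(a) / max(2 * pnorm(a) - 1, 1e-6)
      sigma2 <- v / max(shrink, 0.5)
    }
    ## the source camera contributes px^2/12 twice: once from pixel
    ## integration at acquisition, once from the staircase that
    ## nearest-neighbour resampling spreads across each source pixel
    bws[b] <- sqrt(12 * max(sigma2 - psfSigma^2 - sourcePixelSize^2 / 6,
                            pixelSize^2 / 12))
  }
  fallback <- if (any(is.finite(bws))) median(bws, na.rm = TRUE)
              else 2.355 * psfSigma / 2   # half the PSF FWHM, last resort
  bws[!is.finite(bws)] <- fallback
  for (b in seq_along(centers)) {
    rows <- y[abs(y - centers[b]) * pixelSize <= bws[b] / 2]
    mask[rows, ] <- TRUE
  }
  mask
}

#' Fraction of clusters aligned with the z-disk
#'
#' A cluster is aligned when the pixel containing its centroid lies on the
#' z-disk mask.
#'
#' @param set a [ClusterSet-class].
#' @param zmask a [ZDiskMask-class] on the same pixel grid.
#' @return percentage of aligned clusters (0-100); `NA` for an empty set.
#' @export
clusterZdiskAlignment <- function(set, zmask) {
  stopifnot(is(set, "ClusterSet"), is(zmask, "ZDiskMask"))
  if (set@pixelSize != zmask@pixelSize)
    stop("cluster set and z-disk mask are on different pixel grids", call. = FALSE)
  cl <- set@clusters
  if (!nrow(cl)) return(NA_real_)
  rows <- pmin(nrow(zmask@mask), pmax(1L, ceiling(cl$centroid_y_nm / set@pixelSize)))
  cols <- pmin(ncol(zmask@mask), pmax(1L, ceiling(cl$centroid_x_nm / set@pixelSize)))
  100 * mean(zmask@mask[cbind(rows, cols)])
}

#' Fraction of RyR2 labeling near the z-disk
#'
#' The fraction of total rendered RyR2 intensity lying on pixels whose
#' distance to the z-disk mask is at most `distance` nm. `distance = 0`
#' gives the co-localized fraction; a distance beyond the field diagonal
#' gives 1. Non-decreasing in `distance` by construction.
#'
#' @param ryr the rendered RyR2 [RenderedImage-class].
#' @param zmask a [ZDiskMask-class] on the same grid and dimensions.
#' @param distance window in nm (default 300).
#' @return a fraction in [0, 1]; `NA` for a zero-intensity image.
#' @export
labelingFractionNearZdisk <- function(ryr, zmask, distance = 300) {
  stopifnot(is(ryr, "RenderedImage"), is(zmask, "ZDiskMask"))
  assertScalar(distance, "distance", lo = 0)
  img <- toDensity(ryr)
  if (!identical(dim(img@pixels), dim(zmask@mask)))
    stop("RyR2 image and z-disk mask dimensions differ", call. = FALSE)
  tot <- sum(img@pixels)
  if (tot == 0) return(NA_real_)
  sum(img@pixels[zmask@distanceMap <= distance]) / tot
}
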