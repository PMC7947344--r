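#' Render localization events into a density-proportional image
#'
#' Every event deposits a unit-mass (times its weight) Gaussian kernel of
#' scale `kernelSigma`, integrated exactly over pixels and renormalized so
#' that truncation and field edges never lose mass: the pre-quantization
#' pixel sum equals the total event weight to floating precision.
#' `kernelSigma = 0` reduces to plain half-open binning. Pixel conventions:
#' 0-based pixels, x to columns, y to rows, pixel i covering
#' `[i*pixelSize, (i+1)*pixelSize)`; an event exactly on the upper field
#' bound falls in the last pixel.
#'
#' @param eventTable an [EventTable-class].
#' @param pixelSize nm per pixel (default 5, the rendering scale of the
#'   acquisition pipeline this emulates).
#' @param kernelSigma rendering kernel scale in nm (default 10).
#' @return a [RenderedImage-class] in density units.
#' @examples
#' sc <- buildScene(simConfig(fieldSize = c(2000, 2000), seed = 5))
#' img <- renderEvents(simulateEvents(sc))
#' sum(pixelMatrix(img))   # equals the number of events
#' @export
renderEvents <- function(eventTable, pixelSize = 5, kernelSigma = 10) {
  stopifnot(is(eventTable, "EventTable"))
  assertScalar(pixelSize, "pixelSize", lo = 0, strict_lo = TRUE)
  assertScalar(kernelSigma, "kernelSigma", lo = 0)
  fs <- eventTable@fieldSize
  nx <- max(1L, ceiling(fs[1] / pixelSize))
  ny <- max(1L, ceiling(fs[2] / pixelSize))
  ev <- eventTable@events
  img <- matrix(0, ny, nx)
  if (!nrow(ev)) {
    return(new("RenderedImage", pixels = img, pixelSize = pixelSize,
               intensityScale = NA_real_, quantized = FALSE))
  }
  bad <- which(ev$x_nm < 0 | ev$x_nm > fs[1] | ev$y_nm < 0 | ev$y_nm > fs[2])
  if (length(bad))
    stop("events outside field bounds at rows: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)

  if (kernelSigma == 0) {
    ix <- pmin(floor(ev$x_nm / pixelSize), nx - 1) + 1L
    iy <- pmin(floor(ev$y_nm / pixelSize), ny - 1) + 1L
    idx <- (ix - 1L) * ny + iy
    acc <- rowsum(ev$weight, idx)
    img[as.integer(rownames(acc))] <- acc[, 1]
  } else {
    r <- max(1L, ceiling(6 * kernelSigma / pixelSize))
    for (k in seq_len(nrow(ev))) {
      cx <- ev$x_nm[k] / pixelSize   # position in pixel units
      cy <- ev$y_nm[k] / pixelSize
      x0 <- max(0L, floor(cx) - r); x1 <- min(nx - 1L, floor(cx) + r)
      y0 <- max(0L, floor(cy) - r); y1 <- min(ny - 1L, floor(cy) + r)
      wx <- diff(pnorm(((x0:(x1 + 1L)) - cx) * pixelSize / kernelSigma))
      wy <- diff(pnorm(((y0:(y1 + 1L)) - cy) * pixelSize / kernelSigma))
      patch <- outer(wy, wx)
      img[(y0:y1) + 1L, (x0:x1) + 1L] <-
        img[(y0:y1) + 1L, (x0:x1) + 1L] + ev$weight[k] * patch / sum(patch)
    }
  }
  new("RenderedImage", pixels = img, pixelSize = pixelSize,
      intensityScale = NA_real_, quantized = FALSE)
}

#' Quantize a density image to 16 bits
#'
#' Applies a linear scale chosen so that the 99.9th percentile of the
#' pre-quantization values maps to 60,000 counts (clipping only the extreme
#' tail while using most of the 16-bit range); the scale is recorded in the
#' result's `intensityScale` so counts convert back to density units.
#'
#' @param image a [RenderedImage-class] in density units.
#' @param scale optional explicit counts-per-density-unit scale.
#' @return a quantized [RenderedImage-class].
#' @export
quantizeImage <- function(image, scale = NULL) {
  stopifnot(is(image, "RenderedImage"))
  if (image@quantized) return(image)
  if (is.null(scale)) {
    pos <- image@pixels[image@pixels > 0]
    scale <- if (length(pos)) 60000 / as.numeric(quantile(pos, 0.999)) else 1
  }
  q <- pmin(round(image@pixels * scale), 65535)
  new("RenderedImage", pixels = q, pixelSize = image@pixelSize,
      intensityScale = scale, quantized = TRUE)
}

#' @rdname quantizeImage
#' @param x a quantized image to convert back to density units.
#' @export
toDensity <- function(x) {
  stopifnot(is(x, "RenderedImage"))
  if (!x@quantized) return(x)
  new("RenderedImage", pixels = x@pixels / x@intensityScale,
      pixelSize = x@pixelSize, intensityScale = NA_real_, quantized = FALSE)
}

#' 16-bit grayscale TIFF round trip for rendered images
#'
#' Writes the (quantized) image as an uncompressed single-channel 16-bit
#' TIFF; pixel size and intensity scale travel in a JSON sidecar
#' (`<path>.meta.json`). The quantized pixel values round-trip losslessly.
#'
#' @param image a [RenderedImage-class]; quantized on the fly if needed.
#' @param path TIFF path.
#' @return `readRenderedTiff()` the quantized [RenderedImage-class];
#'   `writeRenderedTiff()` the path, invisibly.
#' @export
writeRenderedTiff <- function(image, path) {
  q <- quantizeImage(image)
  tiff::writeTIFF(q@pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_nm = q@pixelSize,
                            intensity_scale = q@intensityScale,
                            bit_depth = 16L),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeRenderedTiff
#' @param pixelSizeNm,intensityScale metadata overrides used when no
#'   sidecar file is present.
#' @export
readRenderedTiff <- function(path, pixelSizeNm = NULL, intensityScale = NULL) {
  px <- round(tiff::readTIFF(path) * 65535)
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta)) {
    m <- jsonlite::read_json(meta)
    if (is.null(pixelSizeNm)) pixelSizeNm <- m$pixel_size_nm
    if (is.null(intensityScale)) intensityScale <- m$intensity_scale
  }
  if (is.null(pixelSizeNm))
    stop("pixel size unknown: supply pixelSizeNm or provide the sidecar file",
         call. = FALSE)
  if (is.null(intensityScale)) intensityScale <- 1
  new("RenderedImage", pixels = matrix(as.numeric(px), nrow(px), ncol(px)),
      pixelSize = as.numeric(pixelSizeNm),
      intensityScale = as.numeric(intensityScale), quantized = TRUE)
}

#' Estimate a segmentation threshold for a rendered image
#'
#' Policies: `"percentile"` (default) returns the given percentile of the
#' nonzero pixel intensities (70th by default); `"otsu"` maximizes
#' between-class variance on the nonzero pixels; `"density"` sets the
#' threshold at `value` localization events per channel footprint — an
#' absolute physical scale on a density-proportional image that does not
#' drift with field occupancy; `"fixed"` passes `value` through unchanged.
#' Thresholds are in the image's own intensity units.
#'
#' @param image a [RenderedImage-class].
#' @param policy threshold policy name.
#' @param value percentile (0-100) for `"percentile"`, events per channel
#'   footprint for `"density"` (default 1), the threshold itself for
#'   `"fixed"`; ignored for `"otsu"`.
#' @param footprint channel footprint in nm^2 for the density policy.
#' @return a scalar intensity threshold.
#' @export
estimateThreshold <- function(image,
                              policy = c("percentile", "otsu", "density",
                                         "fixed"),
                              value = NULL, footprint = 900) {
  stopifnot(is(image, "RenderedImage"))
  policy <- match.arg(policy)
  px <- image@pixels
  if (policy == "fixed") {
    assertScalar(value, "value", lo = 0, strict_lo = TRUE)
    return(value)
  }
  if (policy == "density") {
    if (is.null(value)) value <- 1
    assertScalar(value, "value", lo = 0, strict_lo = TRUE)
    thr <- value * image@pixelSize^2 / footprint
    if (isTRUE(image@quantized)) thr <- thr * image@intensityScale
    return(thr)
  }
  pos <- px[px > 0]
  if (!length(pos)) stop("no signal: image is all zero", call. = FALSE)
  if (policy == "percentile") {
    if (is.null(value)) value <- 70
    assertScalar(value, "value", lo = 0, hi = 100)
    as.numeric(quantile(pos, value / 100))
  } else {
    otsuNonzero(pos)
  }
}

## Otsu's threshold on the nonzero intensities, 256-bin histogram;
## returns a value strictly inside the occupied intensity range.
otsuNonzero <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - lo) / (hi - lo) * nb)), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  muT <- mu[nb]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  kstar <- which.max(sb)
  lo + kstar / nb * (hi - lo)
}
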