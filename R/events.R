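#' Simulate a blinking acquisition from a ground-truth scene
#'
#' Each channel is labeled with probability `labelingEfficiency`; each label
#' blinks a geometric number of times (mean `blinksPerLabel`, support 1, 2,
#' ...), and every blink yields one localization at the channel position
#' plus isotropic Gaussian error of scale `localizationSigma`. Background
#' events are added as a homogeneous Poisson process at `backgroundRate`
#' per square micron. Frames are assigned uniformly over the acquisition.
#' Events falling outside the field of view are discarded, as they would be
#' in a real acquisition. Deterministic for a fixed (config, seed) pair.
#'
#' @param scene a [GroundTruthScene-class].
#' @param config the generating [SimulationConfig-class]; defaults to the
#'   config stored in the scene.
#' @return an [EventTable-class] with unit weights.
#' @examples
#' sc <- buildScene(simConfig(fieldSize = c(3000, 3000), seed = 3))
#' ev <- simulateEvents(sc)
#' head(events(ev))
#' @export
simulateEvents <- function(scene, config = scene@config) {
  validObject(scene)
  withLocalSeed(splitSeed(config@seed, 2L), simulateEventsImpl(scene, config))
}

simulateEventsImpl <- function(scene, config) {
  n <- nrow(scene@channels)
  xs <- numeric(0); ys <- numeric(0)
  if (n > 0 && config@labelingEfficiency > 0) {
    labeled <- which(runif(n) < config@labelingEfficiency)
    if (length(labeled)) {
      nb <- rgeom(length(labeled), prob = 1 / config@blinksPerLabel) + 1L
      idx <- rep(labeled, nb)
      xs <- scene@channels[idx, 1] + rnorm(length(idx), 0, config@localizationSigma)
      ys <- scene@channels[idx, 2] + rnorm(length(idx), 0, config@localizationSigma)
    }
  }
  areaUm2 <- prod(scene@fieldSize) / 1e6
  nbg <- if (config@backgroundRate > 0) rpois(1, config@backgroundRate * areaUm2) else 0L
  if (nbg > 0) {
    xs <- c(xs, runif(nbg, 0, scene@fieldSize[1]))
    ys <- c(ys, runif(nbg, 0, scene@fieldSize[2]))
  }
  keep <- xs >= 0 & xs <= scene@fieldSize[1] & ys >= 0 & ys <= scene@fieldSize[2]
  xs <- xs[keep]; ys <- ys[keep]
  frames <- if (length(xs)) sample.int(config@nFrames, length(xs), replace = TRUE) - 1L else integer(0)
  new("EventTable",
      events = data.frame(x_nm = xs, y_nm = ys, frame = frames,
                          weight = rep(1, length(xs))),
      fieldSize = scene@fieldSize,
      source = "simulated")
}

#' Read and write localization event tables as CSV
#'
#' Columns `x_nm`, `y_nm`, `frame`, `weight`; the field size travels in a
#' JSON sidecar (`<path>.meta.json`) so that a written table re-loads
#' identically.
#'
#' @param x an [EventTable-class].
#' @param path CSV path.
#' @param fieldSize optional numeric(2) override (nm) when no sidecar exists;
#'   defaults to the ceiling of the event extent.
#' @return `readEventsCsv()` an [EventTable-class]; `writeEventsCsv()` the
#'   path, invisibly.
#' @export
writeEventsCsv <- function(x, path) {
  stopifnot(is(x, "EventTable"))
  write.csv(x@events, path, row.names = FALSE)
  jsonlite::write_json(list(field_size_nm = x@fieldSize, source = x@source),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEventsCsv
#' @export
readEventsCsv <- function(path, fieldSize = NULL) {
  ev <- read.csv(path)
  meta <- paste0(path, ".meta.json")
  if (is.null(fieldSize)) {
    fieldSize <- if (file.exists(meta)) {
      unlist(jsonlite::read_json(meta)$field_size_nm)
    } else if (nrow(ev)) {
      c(ceiling(max(ev$x_nm)), ceiling(max(ev$y_nm)))
    } else c(1, 1)
  }
  bad <- which(ev$x_nm < 0 | ev$x_nm > fieldSize[1] |
               ev$y_nm < 0 | ev$y_nm > fieldSize[2])
  if (length(bad))
    stop("events outside field bounds at rows: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  new("EventTable", events = ev, fieldSize = as.numeric(fieldSize),
      source = "file")
}

#' Render the widefield alpha-actinin (z-disk) channel of a scene
#'
#' Z-disk bands are rendered as intensity ridges: each band's top-hat
#' cross-section is convolved with a Gaussian point-spread function of
#' scale `psfSigma` and integrated over pixels, emulating a
#' diffraction-limited widefield image of the alpha-actinin label.
#'
#' @param scene a [GroundTruthScene-class].
#' @param psfSigma PSF scale in nm (default 250, a typical widefield
#'   diffraction limit).
#' @param pixelSize nm per pixel of the widefield camera (default 100).
#' @return a [RenderedImage-class] in density units; all-zero when the
#'   scene has no bands.
#' @export
simulateActininWidefield <- function(scene, psfSigma = 250, pixelSize = 100) {
  assertScalar(psfSigma, "psfSigma", lo = 0)
  assertScalar(pixelSize, "pixelSize", lo = 0, strict_lo = TRUE)
  nx <- max(1L, ceiling(scene@fieldSize[1] / pixelSize))
  ny <- max(1L, ceiling(scene@fieldSize[2] / pixelSize))
  profile <- numeric(ny)
  bands <- scene@zdiskBands
  if (nrow(bands)) {
    yEdges <- (0:ny) * pixelSize
    for (b in seq_len(nrow(bands))) {
      lo <- bands$center[b] - bands$width[b] / 2
      hi <- bands$center[b] + bands$width[b] / 2
      ## pixel integral of the blurred top-hat, via the Gaussian CDF
      f <- function(y) {
        if (psfSigma > 0) {
          psfSigma * (g1((y - lo) / psfSigma) - g1((y - hi) / psfSigma))
        } else {
          pmin(pmax(y, lo), hi) - lo
        }
      }
      profile <- profile + (f(yEdges[-1]) - f(yEdges[-(ny + 1)])) / pixelSize
    }
  }
  new("RenderedImage", pixels = matrix(profile, nrow = ny, ncol = nx),
      pixelSize = pixelSize, intensityScale = NA_real_, quantized = FALSE)
}

## antiderivative of the standard normal CDF: int Phi(t) dt = t Phi(t) + phi(t)
g1 <- function(t) t * pnorm(t) + dnorm(t)
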