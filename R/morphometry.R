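## Cell-size morphometry and clinical normalizations ---------------------

#' Du Bois body surface area
#'
#' BSA (m^2) = 0.007184 x weight^0.425 x height^0.725, with weight in kg
#' and height in cm.
#'
#' @param weightKg,heightCm positive numerics (vectorized).
#' @return BSA in m^2.
#' @examples
#' duBoisBSA(70, 170)
#' @export
duBoisBSA <- function(weightKg, heightCm) {
  if (any(!is.finite(weightKg)) || any(!is.finite(heightCm)) ||
      any(weightKg <= 0) || any(heightCm <= 0))
    stop("weight and height must be positive", call. = FALSE)
  0.007184 * weightKg^0.425 * heightCm^0.725
}

#' Index an atrial volume to body surface area
#'
#' @param volumeMl raw end-systolic volume, mL.
#' @param bsaM2 body surface area, m^2.
#' @return indexed volume, mL per m^2.
#' @export
indexVolume <- function(volumeMl, bsaM2) {
  if (any(bsaM2 <= 0)) stop("BSA must be positive", call. = FALSE)
  volumeMl / bsaM2
}

#' Cell cross-sectional areas from label masks
#'
#' Each labeled region of a confocal-scale label mask is one traced cell in
#' transverse orientation; area is pixel count times the squared pixel
#' size.
#'
#' @param labels integer matrix; 0 = background, k = pixels of cell k.
#' @param pixelSizeUm microns per pixel.
#' @return a list with `areas` (um^2 per cell, named by label) and
#'   `meanArea` (the per-patient summary value); `NA` mean for an empty
#'   mask.
#' @export
cellAreas <- function(labels, pixelSizeUm) {
  assertScalar(pixelSizeUm, "pixelSizeUm", lo = 0, strict_lo = TRUE)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(list(areas = numeric(0), meanArea = NA_real_))
  counts <- tabulate(labels[labels > 0], nbins = max(ids))[ids]
  areas <- counts * pixelSizeUm^2
  names(areas) <- ids
  list(areas = areas, meanArea = mean(areas))
}

#' Generate synthetic cell label masks
#'
#' Test fixture generator: non-overlapping axis-aligned elliptical "cells"
#' with known pixel areas, on a confocal-scale grid.
#'
#' @param n number of cells.
#' @param dim integer(2) mask dimensions.
#' @param radiusRange semi-axis range in pixels.
#' @param seed RNG seed.
#' @return an integer label matrix.
#' @export
syntheticCellLabels <- function(n = 10, dim = c(256, 256),
                                radiusRange = c(6, 14), seed = 1) {
  withLocalSeed(seed, {
    lab <- matrix(0L, dim[1], dim[2])
    placedId <- 0L
    for (k in seq_len(n)) {
      for (try in seq_len(200)) {
        a <- runif(1, radiusRange[1], radiusRange[2])
        b <- runif(1, radiusRange[1], radiusRange[2])
        cx <- runif(1, b + 2, dim[2] - b - 2)
        cy <- runif(1, a + 2, dim[1] - a - 2)
        rows <- which(abs(seq_len(dim[1]) - cy) <= a + 1)
        cols <- which(abs(seq_len(dim[2]) - cx) <= b + 1)
        sel <- outer((rows - cy) / a, (cols - cx) / b,
                     function(u, v) u^2 + v^2) <= 1
        if (any(lab[rows, cols][sel] > 0L)) next
        sub <- lab[rows, cols]
        sub[sel] <- placedId + 1L
        lab[rows, cols] <- sub
        placedId <- placedId + 1L
        break
      }
    }
    lab
  })
}

#' Pearson correlation between paired per-patient values
#'
#' Pearson r with its two-sided p-value from the t transform, as used for
#' the hypertrophy-dilation relationship (per-patient mean cell area
#' against indexed atrial volume).
#'
#' @param x,y paired numeric vectors, no missing pairs, n >= 3.
#' @return a list with `r`, `r2`, `p`, `n`. Zero variance in either
#'   variable gives `NA` with a warning.
#' @examples
#' correlatePatients(1:10, 2 * (1:10) + 1)$r2
#' @export
correlatePatients <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- complete.cases(x, y)
  if (any(!ok)) stop("missing pairs are not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value, n = n)
}

#' Assemble a patient clinical record table
#'
#' Computes Du Bois BSA and BSA-indexed atrial volumes from raw clinical
#' measurements.
#'
#' @param patients data.frame with columns `id`, `group`, `height_cm`,
#'   `weight_kg`, `raesv_ml`, `laesv_ml` (raw end-systolic volumes) and
#'   optionally `mean_cell_area_um2`.
#' @return the table with `bsa_m2`, `raesv_ml_m2`, `laesv_ml_m2` appended.
#' @export
patientRecords <- function(patients) {
  need <- c("id", "group", "height_cm", "weight_kg", "raesv_ml", "laesv_ml")
  if (!all(need %in% names(patients)))
    stop("patient table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  patients$bsa_m2 <- duBoisBSA(patients$weight_kg, patients$height_cm)
  patients$raesv_ml_m2 <- indexVolume(patients$raesv_ml, patients$bsa_m2)
  patients$laesv_ml_m2 <- indexVolume(patients$laesv_ml, patients$bsa_m2)
  patients
}
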