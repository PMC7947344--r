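#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats quantile rnorm runif rpois rgeom rbinom pnorm qnorm
#'   dnorm uniroot cor.test shapiro.test oneway.test aov kruskal.test
#'   TukeyHSD ptukey pchisq pf pt sd var median dist setNames p.adjust
#'   complete.cases
#' @importFrom utils read.csv write.csv head tail combn
NULL

## Deterministic per-stage seed derivation: one user-facing seed, a distinct
## 31-bit stream seed per pipeline stage (Lehmer-style mixing).
splitSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.numeric(seed)) %% 2147483647)
  for (k in seq_len(stage)) {
    s <- (s * 48271 + 2654435 * stage + k) %% 2147483647
  }
  as.integer(max(1, s))
}

## Evaluate an expression under a local, restored RNG state.
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

assertScalar <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lo && x <= lo)
    stop(sprintf("'%s' must be > %g", name, lo), call. = FALSE)
  if (!strict_lo && x < lo)
    stop(sprintf("'%s' must be >= %g", name, lo), call. = FALSE)
  if (x > hi)
    stop(sprintf("'%s' must be <= %g", name, hi), call. = FALSE)
  invisible(x)
}

## FNV-1a hash of a character scalar, reported as 8 hex digits.  Used to
## fingerprint configurations in output tables so mismatched joins are caught.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n"))) %% 256
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); keep h as a double
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    ## 32-bit modular multiply by 16777619, done in two 16-bit halves
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- ((lo * 16777619) %% 4294967296 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## min distance between two point sets (rows = points), plain and exact
minPairDist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  ## blockwise to bound memory on big clusters
  best <- Inf
  step <- 2048L
  for (i0 in seq(1L, nrow(a), by = step)) {
    ai <- a[i0:min(nrow(a), i0 + step - 1L), , drop = FALSE]
    d2 <- outer(ai[, 1], b[, 1], "-")^2 + outer(ai[, 2], b[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}
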