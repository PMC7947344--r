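## Independent brute-force oracles used across the suite. These never call
## the production code paths they check.

## minimal edge-to-edge pixel distance between two pixel-coordinate sets,
## exhaustive over all pairs
oracleMinDist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2)
    best <- min(best, min(d))
  }
  best
}

## per-label nearest-neighbour distances on a label image, brute force over
## all boundary-pixel pairs (a pixel is boundary if any 4-neighbour differs)
oracleNndPixels <- function(lab) {
  k <- max(lab)
  coords <- oracleBoundaryCoords(lab)
  out <- rep(NA_real_, k)
  if (k < 2) return(out)
  for (i in seq_len(k)) {
    best <- Inf
    for (j in seq_len(k)) {
      if (i == j) next
      best <- min(best, oracleMinDist(coords[[i]], coords[[j]]))
    }
    out[i] <- best
  }
  out
}

oracleBoundaryCoords <- function(lab) {
  k <- max(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  lapply(seq_len(k), function(i) {
    idx <- which(lab == i)
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    keep <- logical(length(idx))
    for (t in seq_along(idx)) {
      rr <- r[t]; cc <- c[t]
      nb <- c(if (rr > 1) lab[rr - 1, cc] else 0L,
              if (rr < nr) lab[rr + 1, cc] else 0L,
              if (cc > 1) lab[rr, cc - 1] else 0L,
              if (cc < nc) lab[rr, cc + 1] else 0L)
      keep[t] <- any(nb != i)
    }
    if (!any(keep)) keep[] <- TRUE
    cbind(r[keep], c[keep])
  })
}

## connected components of the pairwise edge-distance graph at a cutoff
## (pixel units), exhaustive
oracleGraphGroups <- function(lab, cutoffPx) {
  k <- max(lab)
  coords <- oracleBoundaryCoords(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (oracleMinDist(coords[[i]], coords[[j]]) <= cutoffPx) {
        a <- find(i); b <- find(j)
        if (a != b) parent[b] <- a
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

## random blob mask on an n x n grid: k discs of random radius
randomBlobMask <- function(n = 256, k = 8, rRange = c(2, 8)) {
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(k)) {
    r <- runif(1, rRange[1], rRange[2])
    cy <- runif(1, r + 1, n - r - 1); cx <- runif(1, r + 1, n - r - 1)
    rows <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
    sel <- outer(rows - cy, cols - cx, function(a, b) a^2 + b^2) <= r^2
    mask[rows, cols][sel] <- TRUE
  }
  mask
}

## do two labelings/groupings induce the same partition?
samePartition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(match(a, unique(a))),
              as.integer(match(b, unique(b))))
}

## independent 8-connected labeling by BFS flood fill
oracleLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

## wrap a label matrix in a minimal ClusterSet for distance/grouping tests
clusterSetFromLabels <- function(lab, pixelSize = 5) {
  img <- new("RenderedImage", pixels = matrix(as.numeric(lab > 0), nrow(lab)),
             pixelSize = pixelSize, intensityScale = NA_real_,
             quantized = FALSE)
  segmentClusters(img, threshold = 0.5, minEvents = 0)
}

## deterministic tiny event table
miniEvents <- function(xy, fieldSize = c(100, 100), weight = 1) {
  new("EventTable",
      events = data.frame(x_nm = xy[, 1], y_nm = xy[, 2],
                          frame = rep(0L, nrow(xy)),
                          weight = rep(weight, length.out = nrow(xy))),
      fieldSize = fieldSize, source = "simulated")
}
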