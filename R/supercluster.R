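## Super-cluster (calcium release unit) grouping -------------------------

#' Group clusters into super-clusters at a Euclidean cutoff
#'
#' Two clusters belong to the same super-cluster when they are chained by
#' edge-to-edge distances at or below `cutoff` (default 150 nm), i.e. the
#' groups are connected components of the pairwise-distance graph.
#' Candidate groups are generated in O(pixels) by thresholding the exact
#' Euclidean distance transform of the binary mask at `cutoff/2` plus a
#' one-pixel guard band and labeling the dilated mask; exact pairwise
#' edge distances within each candidate group then confirm the edges, so
#' the result equals the brute-force graph partition while only a small
#' fraction of cluster pairs is ever measured.
#'
#' @param set a [ClusterSet-class].
#' @param cutoff grouping cutoff in nm.
#' @return a [SuperClusterSet-class]; group ids follow cluster order.
#' @export
groupSuperclusters <- function(set, cutoff = 150) {
  stopifnot(is(set, "ClusterSet"))
  assertScalar(cutoff, "cutoff", lo = 0, strict_lo = TRUE)
  k <- nrow(set@clusters)
  psz <- set@pixelSize
  emptyGroups <- data.frame(group = integer(0), n_members = integer(0),
                            nnd_edge_nm = numeric(0))
  if (k == 0L)
    return(new("SuperClusterSet", membership = integer(0),
               groups = emptyGroups, cutoff = cutoff))
  lab <- set@labels
  cutPx <- cutoff / psz

  ## candidate generation: half-cutoff dilation (+1 px guard) of the mask
  mask <- lab > 0L
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask)))
  cand <- label8(d <= cutPx / 2 + 1)
  firstPix <- match(seq_len(k), lab[lab > 0L])
  candOf <- cand[which(lab > 0L)][firstPix]

  ## exact confirmation inside candidate groups, on boundary pixels
  bnd <- boundaryPixels(lab)
  bndBy <- lapply(split(seq_len(nrow(bnd)), factor(bnd$id, levels = seq_len(k))),
                  function(ii) cbind(bnd$row[ii], bnd$col[ii]))
  edges <- matrix(integer(0), 0, 2)
  for (g in unique(candOf)) {
    mem <- which(candOf == g)
    if (length(mem) < 2L) next
    for (a in seq_along(mem)[-length(mem)]) {
      for (b in (a + 1L):length(mem)) {
        i <- mem[a]; j <- mem[b]
        dij <- minPairDist(bndBy[[i]], bndBy[[j]])
        if (dij <= cutPx) edges <- rbind(edges, c(i, j))
      }
    }
  }
  member <- ufComponents(k, edges)
  nG <- max(member)

  ## per-group nearest-neighbour distance on the group-labeled image
  glab <- lab
  glab[lab > 0L] <- member[lab[lab > 0L]]
  gn <- nndOfLabels(glab) * psz
  groups <- data.frame(group = seq_len(nG),
                       n_members = tabulate(member, nbins = nG),
                       nnd_edge_nm = if (nG > 1L) gn else NA_real_)
  new("SuperClusterSet", membership = as.integer(member), groups = groups,
      cutoff = cutoff)
}

#' Summary metrics of a super-cluster grouping
#'
#' Returns the headline calcium-release-unit statistics: the percentage of
#' clusters whose nearest neighbour lies within the cutoff (computed from
#' per-cluster edge distances, border-touching clusters excluded), the
#' mean number of member clusters per super-cluster (singletons count as
#' groups of one), the percentage of clusters sitting in multi-member
#' groups (an alternative within-cutoff reading, reported alongside), and
#' the mean edge-to-edge distance between a super-cluster and its nearest
#' neighbouring super-cluster.
#'
#' @param sc a [SuperClusterSet-class].
#' @param set the originating [ClusterSet-class] with
#'   `nearestNeighborDistances()` applied.
#' @return a list with `pctWithinCutoff`, `meanMembers`, `pctInMultiGroup`,
#'   `meanGroupNnd` (NA with a single group).
#' @export
superclusterMetrics <- function(sc, set) {
  stopifnot(is(sc, "SuperClusterSet"), is(set, "ClusterSet"))
  cl <- set@clusters
  if (nrow(cl) != length(sc@membership))
    stop("super-cluster set does not match the cluster set", call. = FALSE)
  nnd <- cl$nnd_edge_nm
  if (nrow(cl) >= 2L && all(is.na(nnd)))
    stop("run nearestNeighborDistances() on the cluster set first", call. = FALSE)
  interior <- !cl$touches_border
  pctWithin <- if (any(interior))
    100 * mean(nnd[interior] <= sc@cutoff, na.rm = TRUE) else NA_real_
  multi <- sc@groups$n_members[sc@membership] > 1L
  gn <- sc@groups$nnd_edge_nm
  list(pctWithinCutoff = pctWithin,
       meanMembers = mean(sc@groups$n_members),
       pctInMultiGroup = if (length(multi)) 100 * mean(multi) else NA_real_,
       meanGroupNnd = if (nrow(sc@groups) > 1L) mean(gn[is.finite(gn)])
                      else NA_real_)
}

#' Write a super-cluster group CSV
#'
#' One row per group: id, member count, member cluster ids
#' (semicolon-separated), and the group's nearest-neighbour distance.
#'
#' @param sc a [SuperClusterSet-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeSuperclustersCsv <- function(sc, path) {
  mem <- split(seq_along(sc@membership), sc@membership)
  df <- data.frame(group = sc@groups$group,
                   n_members = sc@groups$n_members,
                   member_ids = vapply(mem, paste, character(1), collapse = ";"),
                   nnd_edge_nm = sc@groups$nnd_edge_nm)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
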