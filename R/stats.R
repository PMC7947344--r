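## Hierarchical aggregation, group comparisons, blinding -----------------

#' Aggregate a long-format study table
#'
#' Metrics are measured per cluster, clusters sit in images, images in
#' patients: per-cluster values are averaged per image, then per-image
#' values are averaged (unweighted by cluster count) per patient. The
#' patient is the unit of analysis for all group statistics.
#'
#' @param table data.frame with columns `patient`, `group`, `image`,
#'   `metric`, `value` (cluster- or image-level rows).
#' @param level `"image"` for per-image means, `"patient"` for the full
#'   two-stage aggregation.
#' @return an aggregated data.frame at the requested level. Patients whose
#'   every value is missing are dropped with a warning.
#' @export
aggregateStudy <- function(table, level = c("patient", "image")) {
  level <- match.arg(level)
  need <- c("patient", "group", "image", "metric", "value")
  if (!all(need %in% names(table)))
    stop("study table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  byImage <- stats::aggregate(value ~ patient + group + image + metric,
                              data = table, FUN = mean, na.rm = TRUE,
                              na.action = stats::na.pass)
  if (level == "image") return(byImage)
  byPatient <- stats::aggregate(value ~ patient + group + metric,
                                data = byImage, FUN = mean, na.rm = TRUE,
                                na.action = stats::na.pass)
  empty <- !is.finite(byPatient$value)
  if (any(empty)) {
    warning("dropping patient/metric cells with no finite values: ",
            paste(unique(byPatient$patient[empty]), collapse = ", "))
    byPatient <- byPatient[!empty, , drop = FALSE]
  }
  byPatient
}

## Dunn's rank-based post hoc for Kruskal-Wallis, tie-corrected,
## Bonferroni-adjusted (no base-R implementation exists).
dunnPosthoc <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             statistic = z,
             p_adj = pmin(1, p * ncol(pairs)),
             method = "Dunn (Bonferroni)")
}

## Games-Howell post hoc for the Welch branch: studentized-range test with
## per-pair Welch-Satterthwaite degrees of freedom.
gamesHowellPosthoc <- function(values, groups) {
  g <- factor(groups)
  m <- tapply(values, g, mean)
  v <- tapply(values, g, var)
  n <- tapply(values, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  stat <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se2 <- v[[i]] / n[[i]] + v[[j]] / n[[j]]
    t <- abs(m[[i]] - m[[j]]) / sqrt(se2)
    df <- se2^2 / ((v[[i]] / n[[i]])^2 / (n[[i]] - 1) +
                   (v[[j]] / n[[j]])^2 / (n[[j]] - 1))
    stat[k] <- t
    p[k] <- ptukey(t * sqrt(2), nmeans = length(lev), df = df,
                   lower.tail = FALSE)
  }
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             statistic = stat, p_adj = p, method = "Games-Howell")
}

tukeyPosthoc <- function(values, groups) {
  fit <- aov(values ~ g, data = data.frame(values = values, g = factor(groups)))
  tk <- TukeyHSD(fit)$g
  data.frame(comparison = sub("-", " vs ", rownames(tk), fixed = TRUE),
             statistic = tk[, "diff"], p_adj = tk[, "p adj"],
             method = "Tukey HSD", row.names = NULL)
}

#' Compare per-patient values across groups
#'
#' The group-comparison decision tree: Shapiro-Wilk normality per group at
#' `alpha` (any failure sends the metric to Kruskal-Wallis with Dunn post
#' hoc); otherwise Brown-Forsythe-Levene variance homogeneity at `alpha`
#' (failure sends it to Welch ANOVA with Games-Howell); otherwise one-way
#' ANOVA with Tukey HSD. The full decision path is logged in the result.
#' A group whose values are all identical cannot be tested for normality
#' and is treated as not rejecting it.
#'
#' @param values numeric per-patient values.
#' @param groups group label per value (>= 2 groups, each n >= 3).
#' @param alpha gate and significance level (default 0.05).
#' @param metric metric name carried into the result.
#' @return a [GroupComparison-class].
#' @export
compareGroups <- function(values, groups, alpha = 0.05, metric = "metric") {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  n <- tapply(values, g, length)
  small <- names(n)[is.na(n) | n < 3]
  if (length(small))
    stop("groups with fewer than 3 patients: ",
         paste(small, collapse = ", "), call. = FALSE)
  path <- character(0)

  shapP <- vapply(levels(g), function(l) {
    x <- values[g == l]
    if (length(unique(x)) < 3) return(NA_real_)  # degenerate: cannot test
    shapiro.test(x)$p.value
  }, numeric(1))
  normal <- all(is.na(shapP) | shapP >= alpha)
  path <- c(path, sprintf("Shapiro-Wilk per group: min p = %.4g -> %s",
                          suppressWarnings(min(shapP, na.rm = TRUE)),
                          if (normal) "normal" else "non-normal"))

  if (!normal) {
    kw <- kruskal.test(values, g)
    test <- "Kruskal-Wallis"
    stat <- unname(kw$statistic); p <- kw$p.value
    post <- dunnPosthoc(values, g)
    path <- c(path, "branch: Kruskal-Wallis + Dunn post hoc")
  } else {
    lev <- car::leveneTest(values ~ g, center = median)
    levP <- lev[1, "Pr(>F)"]
    eqVar <- is.na(levP) || levP >= alpha
    path <- c(path, sprintf("Brown-Forsythe-Levene: p = %.4g -> %s",
                            levP, if (eqVar) "equal variance" else "unequal variance"))
    if (!eqVar) {
      wt <- oneway.test(values ~ g, var.equal = FALSE)
      test <- "Welch ANOVA"
      stat <- unname(wt$statistic); p <- wt$p.value
      post <- gamesHowellPosthoc(values, g)
      path <- c(path, "branch: Welch ANOVA + Games-Howell post hoc")
    } else {
      fit <- aov(values ~ g)
      tab <- summary(fit)[[1]]
      test <- "one-way ANOVA"
      stat <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
      post <- tukeyPosthoc(values, g)
      path <- c(path, "branch: one-way ANOVA + Tukey HSD post hoc")
    }
  }
  summ <- data.frame(group = levels(g),
                     n = as.integer(n),
                     mean = as.numeric(tapply(values, g, mean)),
                     sem = as.numeric(tapply(values, g, sd) / sqrt(n)))
  new("GroupComparison", metric = metric, summary = summ, test = test,
      statistic = as.numeric(stat), p = as.numeric(p), posthoc = post,
      path = path)
}

#' Blind and unblind group labels
#'
#' `blindGroups()` replaces group labels with opaque codes so downstream
#' analysis can proceed blinded; the key (kept separately) restores them
#' exactly. `unblindGroups()` refuses a wrong key outright — no partial
#' restoration.
#'
#' @param table data.frame with a `group` column.
#' @param seed seed for code assignment; different seeds give different
#'   codes.
#' @param key the key returned by `blindGroups()`.
#' @return `blindGroups()`: list with `table` (codes in `group`) and `key`
#'   (data.frame `code`, `group`, plus a checksum attribute);
#'   `unblindGroups()`: the restored table.
#' @export
blindGroups <- function(table, seed = 1) {
  stopifnot("group" %in% names(table))
  groups <- sort(unique(as.character(table$group)))
  codes <- withLocalSeed(splitSeed(seed, 9L), {
    vapply(seq_along(groups), function(i)
      paste0("X", paste(sample(LETTERS, 8, replace = TRUE), collapse = "")),
      character(1))
  })
  key <- data.frame(code = codes, group = groups, stringsAsFactors = FALSE)
  attr(key, "checksum") <- fnv1a(paste(codes, groups, collapse = "|"))
  out <- table
  out$group <- codes[match(as.character(table$group), groups)]
  list(table = out, key = key)
}

#' @rdname blindGroups
#' @export
unblindGroups <- function(table, key) {
  stopifnot("group" %in% names(table))
  if (!is.data.frame(key) || !all(c("code", "group") %in% names(key)) ||
      !identical(attr(key, "checksum"),
                 fnv1a(paste(key$code, key$group, collapse = "|"))))
    stop("invalid blinding key", call. = FALSE)
  codes <- unique(as.character(table$group))
  if (!all(codes %in% key$code))
    stop("key does not match this table: unknown codes present", call. = FALSE)
  out <- table
  out$group <- key$group[match(as.character(table$group), key$code)]
  out
}

#' Format a grouped study report
#'
#' Emits, per metric, group means +/- SEM over patients, the selected test
#' and its p-value, and a provenance footer (# clusters analyzed,
#' # images(# patients)) — the layout of a nanoscale clustering summary
#' table.
#'
#' @param patientTable per-patient long table (`patient`, `group`,
#'   `metric`, `value`).
#' @param comparisons list of [GroupComparison-class], one per metric.
#' @param provenance optional data.frame (`group`, `n_clusters`,
#'   `n_images`, `n_patients`) for the footer.
#' @return list with `csv` (a data.frame) and `text` (aligned lines).
#' @export
reportTables <- function(patientTable, comparisons, provenance = NULL) {
  groups <- sort(unique(as.character(patientTable$group)))
  rows <- list()
  for (cmp in comparisons) {
    cells <- setNames(rep("", length(groups)), groups)
    for (i in seq_len(nrow(cmp@summary))) {
      gr <- cmp@summary$group[i]
      cells[gr] <- sprintf("%.2f +/- %.2f", cmp@summary$mean[i],
                           cmp@summary$sem[i])
    }
    rows[[length(rows) + 1L]] <-
      c(metric = cmp@metric, as.list(cells),
        test = cmp@test, p = sprintf("%.4f", cmp@p))
  }
  csv <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  if (is.null(csv))
    csv <- as.data.frame(setNames(
      rep(list(character(0)), length(groups) + 3L),
      c("metric", groups, "test", "p")), check.names = FALSE)
  if (!is.null(provenance)) {
    foot1 <- c(metric = "# clusters analyzed",
               as.list(setNames(as.character(
                 provenance$n_clusters[match(groups, provenance$group)]),
                 groups)), test = "", p = "")
    foot2 <- c(metric = "# images(# patients)",
               as.list(setNames(sprintf("%d(%d)",
                 provenance$n_images[match(groups, provenance$group)],
                 provenance$n_patients[match(groups, provenance$group)]),
                 groups)), test = "", p = "")
    csv <- rbind(csv, as.data.frame(foot1, check.names = FALSE),
                 as.data.frame(foot2, check.names = FALSE))
  }
  widths <- vapply(names(csv), function(cn)
    max(nchar(c(cn, as.character(csv[[cn]])))), numeric(1))
  fmtRow <- function(vals) paste(mapply(formatC, as.character(vals),
                                        width = widths, flag = "-"),
                                 collapse = "  ")
  text <- c(fmtRow(names(csv)),
            vapply(seq_len(nrow(csv)), function(i) fmtRow(csv[i, ]),
                   character(1)))
  list(csv = csv, text = text)
}

#' Write a report to disk
#'
#' @param report result of [reportTables()].
#' @param comparisons the comparisons that produced it (decision paths are
#'   logged as JSON).
#' @param pathPrefix output prefix; writes `<prefix>.csv`, `<prefix>.txt`
#'   and `<prefix>_decisions.json`.
#' @return the prefix, invisibly.
#' @export
writeReport <- function(report, comparisons, pathPrefix) {
  write.csv(report$csv, paste0(pathPrefix, ".csv"), row.names = FALSE)
  writeLines(report$text, paste0(pathPrefix, ".txt"))
  log <- lapply(comparisons, function(cmp)
    list(metric = cmp@metric, test = cmp@test, p = cmp@p, path = cmp@path))
  jsonlite::write_json(log, paste0(pathPrefix, "_decisions.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pathPrefix)
}
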