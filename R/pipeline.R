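## Pipeline configuration and end-to-end drivers -------------------------

#' Analysis pipeline configuration
#'
#' Bundles every tunable of the render/segment/group/z-disk/statistics
#' chain, round-trips through YAML losslessly, and carries a content hash
#' ([configHash()]) that is stamped into every output table so results
#' from mismatched configurations are never joined silently.
#'
#' @param pixelSize rendering scale, nm/pixel.
#' @param kernelSigma rendering kernel, nm.
#' @param thresholdPolicy,thresholdValue see [estimateThreshold()].
#' @param minEvents minimum events per retained cluster.
#' @param footprint channel footprint, nm^2.
#' @param superclusterCutoff grouping cutoff, nm.
#' @param zdiskWindow labeling-distribution window, nm.
#' @param closingRadius analysis-area closing radius, nm.
#' @param zdiskPolicy,psfSigma see [segmentZdisks()].
#' @param widefieldPixelSize widefield camera scale, nm/pixel.
#' @param alpha significance and gate level for statistics.
#' @param seed pipeline seed.
#' @return a `PipelineConfig` (named list with a class attribute).
#' @export
pipelineConfig <- function(pixelSize = 5, kernelSigma = 7.5,
                           thresholdPolicy = "density",
                           thresholdValue = 1,
                           minEvents = 2, footprint = 900,
                           superclusterCutoff = 150, zdiskWindow = 300,
                           closingRadius = 1000,
                           zdiskPolicy = "ridge", psfSigma = 250,
                           widefieldPixelSize = 100,
                           alpha = 0.05, seed = 1) {
  cfg <- list(pixel_size_nm = pixelSize, kernel_sigma_nm = kernelSigma,
              threshold_policy = thresholdPolicy,
              threshold_value = thresholdValue,
              min_events = minEvents, footprint_nm2 = footprint,
              supercluster_cutoff_nm = superclusterCutoff,
              zdisk_window_nm = zdiskWindow,
              closing_radius_nm = closingRadius,
              zdisk_policy = zdiskPolicy, psf_sigma_nm = psfSigma,
              widefield_pixel_size_nm = widefieldPixelSize,
              alpha = alpha, seed = as.integer(seed))
  for (f in c("pixel_size_nm", "kernel_sigma_nm", "min_events",
              "footprint_nm2", "supercluster_cutoff_nm", "zdisk_window_nm"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
  if (cfg$supercluster_cutoff_nm <= 0 || cfg$pixel_size_nm <= 0)
    stop("cutoffs and pixel size must be positive", call. = FALSE)
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @export
configHash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

#' @rdname pipelineConfig
#' @param path YAML path.
#' @export
writePipelineConfigYaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  pipelineConfig(pixelSize = x$pixel_size_nm, kernelSigma = x$kernel_sigma_nm,
                 thresholdPolicy = x$threshold_policy,
                 thresholdValue = x$threshold_value,
                 minEvents = x$min_events, footprint = x$footprint_nm2,
                 superclusterCutoff = x$supercluster_cutoff_nm,
                 zdiskWindow = x$zdisk_window_nm,
                 closingRadius = x$closing_radius_nm,
                 zdiskPolicy = x$zdisk_policy, psfSigma = x$psf_sigma_nm,
                 widefieldPixelSize = x$widefield_pixel_size_nm,
                 alpha = x$alpha, seed = x$seed)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig (hash", configHash(x), ")\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}

#' Simulate a full acquisition bundle to disk
#'
#' Builds the scene, simulates the blinking acquisition and the widefield
#' alpha-actinin channel, renders the dSTORM image, and writes the lot:
#' config YAML, scene JSON + channel CSV, event CSV (+ metadata sidecar),
#' rendered and widefield TIFFs, and a ground-truth metric CSV. Re-running
#' with the same config and seed reproduces every file byte for byte.
#'
#' @param simCfg a [SimulationConfig-class].
#' @param outdir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param pipeCfg a `PipelineConfig` supplying the rendering scale.
#' @param dryRun validate and report without writing anything.
#' @return named list of written paths (empty for a dry run), invisibly.
#' @export
runSimulate <- function(simCfg, outdir, prefix = "sim",
                        pipeCfg = pipelineConfig(), dryRun = FALSE) {
  validObject(simCfg)
  if (dryRun) {
    message("config valid; dry run, nothing written")
    return(invisible(list()))
  }
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  p <- function(...) file.path(outdir, paste0(prefix, ...))
  scene <- buildScene(simCfg)
  ev <- simulateEvents(scene)
  img <- renderEvents(ev, pixelSize = pipeCfg$pixel_size_nm,
                      kernelSigma = pipeCfg$kernel_sigma_nm)
  act <- simulateActininWidefield(scene, psfSigma = pipeCfg$psf_sigma_nm,
                                  pixelSize = pipeCfg$widefield_pixel_size_nm)
  paths <- list(config = p("_config.yaml"), scene = p("_scene.json"),
                events = p("_events.csv"), ryr = p("_ryr.tif"),
                actinin = p("_actinin.tif"), truth = p("_truth.csv"))
  writeSimConfigYaml(simCfg, paths$config)
  writeSceneJson(scene, paths$scene)
  writeEventsCsv(ev, paths$events)
  writeRenderedTiff(img, paths$ryr)
  writeRenderedTiff(act, paths$actinin)
  tm <- scene@trueMetrics
  write.csv(data.frame(metric = c("n_channels", "n_clusters",
                                  "mean_cluster_size", "cluster_density",
                                  "pct_within_cutoff",
                                  "clusters_per_supercluster",
                                  "pct_zdisk_aligned", "band_area_fraction"),
                       value = c(tm$nChannels, tm$nClusters,
                                 tm$meanClusterSize, tm$clusterDensity,
                                 tm$pctWithinCutoff,
                                 tm$clustersPerSupercluster,
                                 tm$pctZdiskAligned, tm$bandAreaFraction)),
            paths$truth, row.names = FALSE)
  invisible(paths)
}

#' Analyze one rendered field
#'
#' The single-image core of the pipeline: render (when given events),
#' threshold, segment, measure nearest neighbours, group super-clusters,
#' and quantify z-disk alignment when a widefield channel is supplied.
#'
#' @param input an [EventTable-class] or a [RenderedImage-class].
#' @param actinin optional widefield [RenderedImage-class].
#' @param config a `PipelineConfig`.
#' @return list with `metrics` (named numerics), `set` ([ClusterSet-class]),
#'   `sc` ([SuperClusterSet-class] or NULL) and `zmask`
#'   ([ZDiskMask-class] or NULL).
#' @export
analyzeImage <- function(input, actinin = NULL, config = pipelineConfig()) {
  img <- if (is(input, "EventTable")) {
    renderEvents(input, pixelSize = config$pixel_size_nm,
                 kernelSigma = config$kernel_sigma_nm)
  } else if (is(input, "RenderedImage")) toDensity(input)
  else stop("input must be an EventTable or RenderedImage", call. = FALSE)
  if (all(pixelMatrix(img) == 0))
    stop("no signal: rendered field is empty", call. = FALSE)

  thr <- estimateThreshold(img, policy = config$threshold_policy,
                           value = config$threshold_value,
                           footprint = config$footprint_nm2)
  set <- segmentClusters(img, thr, minEvents = config$min_events,
                         footprint = config$footprint_nm2,
                         closingRadius = config$closing_radius_nm)
  metrics <- c(n_clusters = nClusters(set))
  sc <- NULL; zmask <- NULL
  if (nClusters(set) >= 2L) {
    set <- nearestNeighborDistances(set)
    sc <- groupSuperclusters(set, cutoff = config$supercluster_cutoff_nm)
    sm <- superclusterMetrics(sc, set)
    cl <- clusters(set)
    interior <- !cl$touches_border
    metrics <- c(metrics,
      mean_cluster_size_channels = mean(cl$est_channels),
      cluster_density_per_um2 = clusterDensity(set),
      mean_packing_au = mean(cl$mean_intensity),
      nnd_nm = mean(cl$nnd_edge_nm[interior], na.rm = TRUE),
      pct_within_cutoff = sm$pctWithinCutoff,
      clusters_per_supercluster = sm$meanMembers,
      supercluster_nnd_nm = sm$meanGroupNnd)
  } else if (nClusters(set) == 1L) {
    cl <- clusters(set)
    metrics <- c(metrics,
      mean_cluster_size_channels = mean(cl$est_channels),
      cluster_density_per_um2 = clusterDensity(set),
      mean_packing_au = mean(cl$mean_intensity))
  }
  if (!is.null(actinin) && nClusters(set) > 0L) {
    zmask <- segmentZdisks(actinin, targetPixelSize = set@pixelSize,
                           targetDim = dim(labelMatrix(set)),
                           policy = config$zdisk_policy,
                           psfSigma = config$psf_sigma_nm)
    metrics <- c(metrics,
      pct_zdisk_aligned = clusterZdiskAlignment(set, zmask),
      fraction_colocalized = labelingFractionNearZdisk(img, zmask, 0),
      fraction_within_window = labelingFractionNearZdisk(
        img, zmask, config$zdisk_window_nm))
  }
  list(metrics = metrics, set = set, sc = sc, zmask = zmask)
}

#' Analyze a batch of fields into a per-image summary table
#'
#' @param inputs data.frame with columns `image`, `patient`, `group`, and
#'   either `events_csv` or `ryr_tiff` paths (plus optional
#'   `actinin_tiff`).
#' @param config a `PipelineConfig`.
#' @return per-image summary data.frame (one metric per column), stamped
#'   with the config hash. Images whose rendered field carries no signal
#'   are skipped with a message.
#' @export
runAnalyze <- function(inputs, config = pipelineConfig()) {
  stopifnot(is.data.frame(inputs),
            all(c("image", "patient", "group") %in% names(inputs)))
  rows <- list()
  pxSeen <- numeric(0)
  for (i in seq_len(nrow(inputs))) {
    input <- if ("events_csv" %in% names(inputs) &&
                 !is.na(inputs$events_csv[i]) && nzchar(inputs$events_csv[i])) {
      readEventsCsv(inputs$events_csv[i])
    } else {
      readRenderedTiff(inputs$ryr_tiff[i])
    }
    if (is(input, "RenderedImage")) {
      pxSeen <- c(pxSeen, pixelSize(input))
      if (length(unique(pxSeen)) > 1L)
        stop("mixed pixel sizes across inputs", call. = FALSE)
    }
    actinin <- if ("actinin_tiff" %in% names(inputs) &&
                   !is.na(inputs$actinin_tiff[i]) &&
                   nzchar(inputs$actinin_tiff[i])) {
      readRenderedTiff(inputs$actinin_tiff[i])
    } else NULL
    res <- tryCatch(analyzeImage(input, actinin, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping image ", inputs$image[i], ": ", conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <-
      c(list(image = inputs$image[i], patient = inputs$patient[i],
             group = inputs$group[i], config_hash = configHash(config)),
        as.list(res$metrics))
  }
  if (!length(rows)) return(data.frame())
  nms <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(nms, names(r))] <- NA
    as.data.frame(r[nms], check.names = FALSE)
  }))
  out
}

#' Group statistics over a per-image summary
#'
#' Reshapes a [runAnalyze()] summary to long format, aggregates to the
#' patient level, runs the group-comparison decision tree per metric, and
#' formats the study report with provenance counts.
#'
#' @param summary per-image summary from [runAnalyze()] (a `group` column
#'   of blinded codes is fine: the report then carries codes only).
#' @param config a `PipelineConfig`.
#' @param metrics metric columns to analyze; defaults to every numeric
#'   metric column present.
#' @return list with `patientTable`, `comparisons`, `report`, `provenance`.
#' @export
runStats <- function(summary, config = pipelineConfig(), metrics = NULL) {
  if (!nrow(summary)) {
    return(list(patientTable = data.frame(),
                comparisons = list(),
                report = reportTables(data.frame(patient = character(0),
                                                 group = character(0),
                                                 metric = character(0),
                                                 value = numeric(0)), list()),
                provenance = data.frame()))
  }
  if (!"group" %in% names(summary))
    stop("summary lacks a 'group' column", call. = FALSE)
  if ("config_hash" %in% names(summary) &&
      length(unique(summary$config_hash)) > 1L)
    stop("mixed config hashes in summary; refusing to pool", call. = FALSE)
  drop <- c("image", "patient", "group", "config_hash")
  if (is.null(metrics))
    metrics <- setdiff(names(summary)[vapply(summary, is.numeric, logical(1))],
                       drop)
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(patient = summary$patient, group = summary$group,
               image = summary$image, metric = m, value = summary[[m]])))
  pat <- aggregateStudy(long, level = "patient")
  comparisons <- list()
  for (m in metrics) {
    sub <- pat[pat$metric == m & is.finite(pat$value), , drop = FALSE]
    cnt <- table(sub$group)
    if (length(cnt) < 2 || any(cnt < 3)) next
    comparisons[[m]] <- compareGroups(sub$value, sub$group,
                                      alpha = config$alpha, metric = m)
  }
  prov <- do.call(rbind, lapply(split(summary, summary$group), function(s)
    data.frame(group = s$group[1],
               n_clusters = if ("n_clusters" %in% names(s))
                 sum(s$n_clusters, na.rm = TRUE) else NA_integer_,
               n_images = length(unique(s$image)),
               n_patients = length(unique(s$patient)))))
  report <- reportTables(pat, comparisons, provenance = prov)
  list(patientTable = pat, comparisons = comparisons, report = report,
       provenance = prov)
}
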