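#' Default pipeline configuration
#'
#' Every numeric threshold used by a run lives here; [pipeline_config()]
#' merges a YAML file and `--set key=value` overrides on top.
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 42L,
    log_level = "info",
    paths = list(manifest = NULL, spectra_dir = NULL,
                 output_dir = "sparkspec_out"),
    simulation = list(
      n_patients = 18L, sigma_patient = 0.15, sigma_spectrum = 0.2,
      baseline_level = 30, noise_sd = 5, grid_start_nm = 200,
      grid_end_nm = 800, grid_step_nm = 0.02, qc_fail_fraction = 0.02
    ),
    preprocessing = list(
      baseline = list(inner_halfwidth_nm = 0.15, outer_halfwidth_nm = 0.60,
                      broad_scale = 4),
      qc = list(carbon_snr_min = 20)
    ),
    features = list(
      min_snr = 20, min_occurrence = 0.05, match_tol_nm = 0.05,
      match_tol_broad_nm = 0.5, integration_halfwidth_sigmas = 3
    ),
    classifier = list(cost = 1, gamma = "scale", tol = 1e-3)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

parse_set_value <- function(x) {
  if (x %in% c("true", "TRUE")) return(TRUE)
  if (x %in% c("false", "FALSE")) return(FALSE)
  if (x %in% c("null", "NULL")) return(NULL)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' Load a pipeline configuration
#'
#' @param path YAML config file, or `NULL` for defaults only.
#' @param set character vector of `section.key=value` overrides
#'   (e.g. `"features.min_snr=25"`).
#' @return the merged configuration list.
#' @export
pipeline_config <- function(path = NULL, set = character(0)) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) stop_config("malformed config ",
                                                     path, ": ",
                                                     conditionMessage(e)))
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  for (s in set) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop_config("bad --set expression: ", s)
    keys <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    node <- paste0("cfg", paste0("[['", keys, "']]", collapse = ""))
    eval(parse(text = paste0(node, " <- parse_set_value(kv[2L])")))
  }
  cfg
}

sim_config_from <- function(config) {
  s <- config$simulation
  counts <- if (!is.null(s$per_patient_counts))
    as.data.frame(s$per_patient_counts) else default_patient_counts()
  if (!is.null(s$n_patients) && s$n_patients != nrow(counts) &&
      is.null(s$per_patient_counts))
    counts <- counts[rep_len(seq_len(nrow(counts)), s$n_patients), ,
                     drop = FALSE]
  cohort_config(
    n_patients = s$n_patients %||% nrow(counts),
    per_patient_counts = counts,
    sigma_patient = s$sigma_patient %||% 0.15,
    sigma_spectrum = s$sigma_spectrum %||% 0.2,
    baseline_level = s$baseline_level %||% 30,
    noise_sd = s$noise_sd %||% 5,
    grid_start_nm = s$grid_start_nm %||% 200,
    grid_end_nm = s$grid_end_nm %||% 800,
    grid_step_nm = s$grid_step_nm %||% 0.02,
    qc_fail_fraction = s$qc_fail_fraction %||% 0.02,
    seed = config$seed %||% 42L
  )
}

run_log <- function(config, lines, path) {
  hdr <- c(
    paste0("sparkspec run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    paste0("qc.carbon_snr_min: ",
           config$preprocessing$qc$carbon_snr_min),
    paste0("baseline.inner_halfwidth_nm: ",
           config$preprocessing$baseline$inner_halfwidth_nm),
    paste0("baseline.outer_halfwidth_nm: ",
           config$preprocessing$baseline$outer_halfwidth_nm),
    paste0("baseline.broad_scale: ",
           config$preprocessing$baseline$broad_scale),
    paste0("features.min_snr: ", config$features$min_snr),
    paste0("features.min_occurrence: ", config$features$min_occurrence),
    paste0("features.match_tol_nm: ", config$features$match_tol_nm),
    paste0("features.match_tol_broad_nm: ",
           config$features$match_tol_broad_nm),
    paste0("features.integration_halfwidth_sigmas: ",
           config$features$integration_halfwidth_sigmas),
    paste0("classifier.cost: ", config$classifier$cost),
    paste0("classifier.gamma: ", config$classifier$gamma),
    paste0("classifier.tol: ", config$classifier$tol)
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Writes the manifest, one spectrum file per acquisition and the generating
#' configuration (including the seed) to `paths$output_dir`.
#'
#' @param config a pipeline configuration (see [pipeline_config()]).
#' @return the simulated `oes_cohort`, invisibly.
#' @export
pipeline_simulate <- function(config = pipeline_config()) {
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop_config("cannot create output_dir: ", out)
  sim_cfg <- sim_config_from(config)
  cohort <- simulate_cohort(sim_cfg, default_line_catalogue())
  write_cohort(cohort, out)
  dump_cfg <- unclass(sim_cfg)
  dump_cfg$per_patient_counts <- as.list(dump_cfg$per_patient_counts)
  yaml::write_yaml(dump_cfg, file.path(out, "cohort_config.yaml"))
  message("pipeline_simulate: wrote ", length(cohort$spectra),
          " spectra for ", sim_cfg$n_patients, " patients to ", out)
  invisible(cohort)
}

#' Run the full analysis pipeline
#'
#' QC filtering, carbon-line gating, panel selection, normalization and
#' feature integration, and leave-one-patient-out classification; writes
#' `panel.csv`, `scores.csv`, `metrics.csv`, `predictions.csv`,
#' `report.json` (per-fold confusion counts) and `run_log.txt` to
#' `paths$output_dir`. Any stage failure aborts with the stage name.
#'
#' @param config a pipeline configuration.
#' @param cohort optionally, an in-memory `oes_cohort`; otherwise read from
#'   `paths$manifest` / `paths$spectra_dir`.
#' @return the `lopo_report`, invisibly.
#' @export
pipeline_run <- function(config = pipeline_config(), cohort = NULL) {
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    if (identical(config$log_level, "info")) message(...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_analysis("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (is.null(cohort)) {
    if (is.null(config$paths$manifest))
      stop_config("paths.manifest is required when no cohort is given")
    cohort <- stage("read_cohort",
                    read_cohort(config$paths$manifest,
                                config$paths$spectra_dir %||%
                                  dirname(config$paths$manifest)))
  }
  note("input: ", length(cohort$spectra), " spectra, ",
       length(unique(cohort$patient_ids)), " patients")

  n0 <- length(cohort$spectra)
  cohort <- stage("apply_qc", suppressMessages(apply_qc(cohort)))
  note("apply_qc: excluded ", n0 - length(cohort$spectra),
       " flagged spectra, ", length(cohort$spectra), " retained")

  pp <- config$preprocessing
  gate <- stage("carbon_gate", vapply(
    cohort$spectra, carbon_gate, logical(1L),
    snr_min = pp$qc$carbon_snr_min,
    inner_hw = pp$baseline$inner_halfwidth_nm,
    outer_hw = pp$baseline$outer_halfwidth_nm))
  if (any(!gate)) {
    cohort$qc$status[!gate] <- "low_carbon_snr"
    cohort <- suppressMessages(suppressWarnings(apply_qc(cohort)))
  }
  note("carbon_gate (SNR >= ", pp$qc$carbon_snr_min, "): excluded ",
       sum(!gate), " spectra, ", length(cohort$spectra), " retained")
  if (length(cohort$spectra) == 0L)
    stop_data("no spectra left after the carbon gate")

  ft <- config$features
  panel <- stage("select_panel", select_panel(
    cohort, default_line_catalogue(),
    min_snr = ft$min_snr, min_occurrence = ft$min_occurrence,
    inner_hw = pp$baseline$inner_halfwidth_nm,
    outer_hw = pp$baseline$outer_halfwidth_nm,
    broad_scale = pp$baseline$broad_scale,
    tol_nm = ft$match_tol_nm, tol_broad_nm = ft$match_tol_broad_nm,
    integration_halfwidth_sigmas = ft$integration_halfwidth_sigmas))
  note("select_panel: ", nrow(panel), " lines retained (min_snr > ",
       ft$min_snr, ", occurrence >= ", ft$min_occurrence, ")")
  utils::write.csv(panel, file.path(out, "panel.csv"), row.names = FALSE)

  fm <- stage("build_matrix", build_matrix(
    cohort, panel,
    inner_hw = pp$baseline$inner_halfwidth_nm,
    outer_hw = pp$baseline$outer_halfwidth_nm,
    broad_scale = pp$baseline$broad_scale))
  note("build_matrix: ", nrow(fm$X), " x ", ncol(fm$X))

  if (nlevels(droplevels(fm$labels)) == 2L) {
    scores <- stage("feature_scores", feature_scores(fm))
    utils::write.csv(scores, file.path(out, "scores.csv"),
                     row.names = FALSE)
  }

  report <- stage("run_lopo", suppressMessages(run_lopo(
    fm, cost = config$classifier$cost, gamma = config$classifier$gamma,
    tol = config$classifier$tol)))
  note("run_lopo: mean ",
       paste(names(report$mean), sprintf("%.3f", report$mean), sep = "=",
             collapse = " "))
  if (report$n_undefined > 0L)
    note("run_lopo: ", report$n_undefined,
         " undefined per-patient metric value(s) skipped")

  write_metrics(report, file.path(out, "metrics.csv"))
  preds <- predictions_table(fm, report, config)
  utils::write.csv(preds, file.path(out, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, n_spectra = nrow(fm$X),
         confusion = report$confusion, mean = as.list(report$mean)),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  run_log(config, log_lines, file.path(out, "run_log.txt"))
  invisible(report)
}

## refit per fold to emit per-spectrum predictions (kept out of run_lopo so
## the metric path stays minimal)
predictions_table <- function(fm, report, config) {
  folds <- make_splits(fm)
  labels <- as.character(fm$labels)
  out <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    model <- svc_fit(fm$X[f$train_idx, , drop = FALSE], labels[f$train_idx],
                     cost = config$classifier$cost,
                     gamma = config$classifier$gamma,
                     tol = config$classifier$tol)
    pred <- predict(model, fm$X[f$test_idx, , drop = FALSE])
    out[[k]] <- data.frame(spectrum_id = fm$spectrum_ids[f$test_idx],
                           patient_id = f$test_patient_id,
                           truth = labels[f$test_idx], predicted = pred,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Render a human-readable summary of a metrics file
#'
#' Re-derives the mean row from the per-patient rows, checks it against the
#' stored value, prints a formatted table and optionally renders a
#' patient-by-metric heatmap.
#'
#' @param metrics_path CSV written by [write_metrics()] / [pipeline_run()].
#' @param figure_path optional PNG path for the heatmap.
#' @return the metrics data frame, invisibly.
#' @export
pipeline_report <- function(metrics_path, figure_path = NULL) {
  if (!file.exists(metrics_path))
    stop_data("metrics file not found: ", metrics_path)
  df <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "accuracy", "sensitivity", "specificity", "ppv",
            "npv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("metrics file is missing column(s): ",
              paste(miss, collapse = ", "))
  pat <- df[df$patient_id != "mean", , drop = FALSE]
  stored <- df[df$patient_id == "mean", -1L, drop = FALSE]
  rederived <- vapply(pat[-1L], function(v) mean(v, na.rm = TRUE),
                      numeric(1L))
  if (nrow(stored) == 1L) {
    delta <- abs(unlist(stored) - rederived)
    if (any(delta > 1e-6, na.rm = TRUE))
      stop_data("stored mean row disagrees with re-derived means (max |d| = ",
                format(max(delta, na.rm = TRUE)), ")")
  }
  show <- pat
  show[-1L] <- lapply(show[-1L], function(v) sprintf("%5.1f%%", 100 * v))
  cat("Per-patient leave-one-patient-out performance\n")
  print.data.frame(show, row.names = FALSE)
  cat("mean:", paste(names(rederived),
                     sprintf("%.1f%%", 100 * rederived), sep = "=",
                     collapse = " "), "\n")
  if (!is.null(figure_path)) {
    m <- as.matrix(pat[-1L])
    rownames(m) <- pat$patient_id
    grDevices::png(figure_path, width = 640, height = 960)
    op <- graphics::par(mar = c(5, 6, 2, 1))
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "RdYlGn"))
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 1)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(df)
}
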