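#' Leave-one-patient-out split plan
#'
#' One fold per distinct patient: the fold's test rows are exactly that
#' patient's spectra, the training rows everyone else's. Folds are ordered by
#' sorted patient id, so the plan is deterministic.
#'
#' @param fm a `feature_matrix`.
#' @return list of class `split_plan`; each fold is
#'   `list(test_patient_id, train_idx, test_idx)`.
#' @export
make_splits <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  patients <- sort(unique(fm$patient_ids))
  if (length(patients) < 2L)
    stop_analysis("leave-one-patient-out needs >= 2 patients")
  folds <- lapply(patients, function(p) {
    test <- which(fm$patient_ids == p)
    list(test_patient_id = p,
         train_idx = setdiff(seq_len(nrow(fm$X)), test),
         test_idx = test)
  })
  structure(folds, class = "split_plan")
}

#' Confusion counts for a binary prediction
#'
#' Positive class is `abnormal`: `tp` = abnormal predicted abnormal,
#' `tn` = normal predicted normal.
#'
#' @param truth,pred equal-length vectors over `{normal, abnormal}`.
#' @return named list `tp`, `fp`, `tn`, `fn` (class `confusion_counts`).
#' @export
evaluate_confusion <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop_analysis("truth and prediction lengths differ")
  bad <- setdiff(unique(c(truth, pred)), c("normal", "abnormal"))
  if (length(bad)) stop_analysis("unknown label: ", bad[1L])
  structure(list(
    tp = sum(truth == "abnormal" & pred == "abnormal"),
    fp = sum(truth == "normal" & pred == "abnormal"),
    tn = sum(truth == "normal" & pred == "normal"),
    fn = sum(truth == "abnormal" & pred == "normal")
  ), class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' accuracy = (tp+tn)/n, sensitivity = tp/(tp+fn),
#' specificity = tn/(tn+fp), ppv = tp/(tp+fp), npv = tn/(tn+fn);
#' a metric with zero denominator is `NA` (undefined).
#'
#' @param cc `confusion_counts`.
#' @return named numeric vector of the five metrics.
#' @export
confusion_metrics <- function(cc) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  with(cc, c(
    accuracy = rat(tp + tn, tp + fp + tn + fn),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn)
  ))
}

#' Leave-one-patient-out classification with per-patient metrics
#'
#' For each fold of [make_splits()]: fit [svc_fit()] on all other patients'
#' rows, predict the held-out patient, and score the five diagnostic
#' metrics. A structural no-leakage assertion (no training row carries the
#' test patient id) runs on every fold. The summary row holds the arithmetic
#' mean over patients, skipping undefined (`NA`) entries with a logged count.
#'
#' @param fm a `feature_matrix` with >= 2 patients and both classes.
#' @param cost,gamma,tol classifier hyperparameters, see [svc_fit()].
#' @return object of class `lopo_report`: list with `per_patient` (data
#'   frame: patient_id, the five metrics), `mean` (named numeric),
#'   `confusion` (data frame of per-fold tp/fp/tn/fn), `n_undefined`.
#' @export
run_lopo <- function(fm, cost = 1, gamma = "scale", tol = 1e-3) {
  stopifnot(inherits(fm, "feature_matrix"))
  folds <- make_splits(fm)
  labels <- as.character(fm$labels)
  per <- vector("list", length(folds))
  conf <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    if (any(fm$patient_ids[f$train_idx] == f$test_patient_id))
      stop_analysis("leakage: training rows contain test patient ",
                    f$test_patient_id)
    res <- tryCatch({
      model <- svc_fit(fm$X[f$train_idx, , drop = FALSE],
                       labels[f$train_idx], cost = cost, gamma = gamma,
                       tol = tol)
      pred <- predict(model, fm$X[f$test_idx, , drop = FALSE])
      evaluate_confusion(labels[f$test_idx], pred)
    }, error = function(e) {
      stop_analysis("fold for patient ", f$test_patient_id, ": ",
                    conditionMessage(e))
    })
    conf[[k]] <- data.frame(patient_id = f$test_patient_id, tp = res$tp,
                            fp = res$fp, tn = res$tn, fn = res$fn,
                            stringsAsFactors = FALSE)
    per[[k]] <- data.frame(patient_id = f$test_patient_id,
                           t(confusion_metrics(res)),
                           stringsAsFactors = FALSE)
  }
  per_patient <- do.call(rbind, per)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  means <- vapply(metric_cols,
                  function(m) mean(per_patient[[m]], na.rm = TRUE),
                  numeric(1L))
  n_undef <- sum(is.na(per_patient[metric_cols]))
  if (n_undef > 0L)
    message("run_lopo: ", n_undef,
            " undefined per-patient metric value(s) skipped in the means")
  structure(list(per_patient = per_patient, mean = means,
                 confusion = do.call(rbind, conf), n_undefined = n_undef),
            class = "lopo_report")
}

#' @export
print.lopo_report <- function(x, digits = 3, ...) {
  cat(sprintf("<lopo_report> %d patients\n", nrow(x$per_patient)))
  df <- x$per_patient
  df[-1L] <- lapply(df[-1L], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  cat("mean:", paste(names(x$mean), round(x$mean, digits), sep = "=",
                     collapse = " "), "\n")
  invisible(x)
}

#' Write a metrics report as delimited text
#'
#' One row per patient plus a final `mean` row, columns `patient_id`,
#' `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`.
#'
#' @param report a `lopo_report`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "lopo_report"))
  mean_row <- data.frame(patient_id = "mean", t(report$mean),
                         stringsAsFactors = FALSE)
  out <- rbind(report$per_patient, mean_row)
  utils::write.csv(format(out, digits = 15), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
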