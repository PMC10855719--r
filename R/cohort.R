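#' Acquisition-level QC statuses
#'
#' `ok` spectra enter analysis; the three acquisition categories mirror the
#' exclusion reasons recorded during data collection (fiber contamination,
#' poor spectral quality, spectrometer memory error); `low_carbon_snr` is
#' assigned by [carbon_gate()] during preprocessing.
#'
#' @export
qc_statuses <- c("ok", "instrument_contamination", "poor_spectral_quality",
                 "memory_error", "low_carbon_snr")

#' Construct a cohort of spectra with QC records
#'
#' @param spectra list of [oes_spectrum()] objects.
#' @param qc data frame with columns `spectrum_id`, `status`
#'   (see [qc_statuses]). Defaults to all-`ok`.
#' @return an object of class `oes_cohort`: list with elements `spectra`
#'   (named by spectrum_id) and `qc`.
#' @export
oes_cohort <- function(spectra, qc = NULL) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  ok <- vapply(spectra, inherits, logical(1L), what = "oes_spectrum")
  if (!all(ok)) stop_data("element ", which(!ok)[1L], " is not an oes_spectrum")
  ids <- vapply(spectra, `[[`, character(1L), "spectrum_id")
  pids <- vapply(spectra, `[[`, character(1L), "patient_id")
  if (anyDuplicated(ids))
    stop_data("duplicate spectrum_id: ", ids[duplicated(ids)][1L])
  names(spectra) <- ids
  if (is.null(qc)) {
    qc <- data.frame(spectrum_id = ids, status = "ok",
                     stringsAsFactors = FALSE)
  }
  qc <- as.data.frame(qc, stringsAsFactors = FALSE)
  if (!all(c("spectrum_id", "status") %in% names(qc)))
    stop_data("qc must have columns spectrum_id, status")
  if (!all(qc$status %in% qc_statuses))
    stop_data("unknown QC status: ",
              setdiff(unique(qc$status), qc_statuses)[1L])
  if (anyDuplicated(qc$spectrum_id) || !setequal(qc$spectrum_id, ids))
    stop_data("qc records must match cohort spectra one-to-one")
  qc <- qc[match(ids, qc$spectrum_id), , drop = FALSE]
  rownames(qc) <- NULL
  structure(list(spectra = spectra, qc = qc, patient_ids = pids),
            class = "oes_cohort")
}

#' @export
print.oes_cohort <- function(x, ...) {
  tab <- table(vapply(x$spectra, `[[`, character(1L), "tissue_label"))
  cat(sprintf(
    "<oes_cohort> %d spectra, %d patients (%s); QC ok: %d\n",
    length(x$spectra), length(unique(x$patient_ids)),
    paste(names(tab), tab, sep = "=", collapse = ", "),
    sum(x$qc$status == "ok")
  ))
  invisible(x)
}

#' Cohort manifest as a data frame
#'
#' @param cohort an `oes_cohort`.
#' @return data frame with one row per spectrum: `spectrum_id`, `patient_id`,
#'   `sample_id`, `tissue_label`, `qc_status`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "oes_cohort"))
  data.frame(
    spectrum_id = names(cohort$spectra),
    patient_id = vapply(cohort$spectra, `[[`, character(1L), "patient_id"),
    sample_id = vapply(cohort$spectra, `[[`, character(1L), "sample_id"),
    tissue_label = vapply(cohort$spectra, `[[`, character(1L), "tissue_label"),
    qc_status = cohort$qc$status,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a cohort from a manifest plus a directory of spectrum files
#'
#' The manifest is delimited text with columns `spectrum_id`, `patient_id`,
#' `sample_id`, `tissue_label` (`normal`/`abnormal`), `qc_status` and `file`
#' (path relative to `spectra_dir`).
#'
#' @param manifest_path manifest file.
#' @param spectra_dir directory holding the referenced spectrum files.
#' @return an `oes_cohort`.
#' @export
read_cohort <- function(manifest_path, spectra_dir) {
  if (!file.exists(manifest_path))
    stop_data("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, colClasses = "character",
                         strip.white = TRUE)
  need <- c("spectrum_id", "patient_id", "sample_id", "tissue_label",
            "qc_status", "file")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop_data("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$spectrum_id))
    stop_data("duplicate spectrum_id in manifest: ",
              man$spectrum_id[duplicated(man$spectrum_id)][1L])
  bad_lab <- setdiff(unique(man$tissue_label), c("normal", "abnormal"))
  if (length(bad_lab))
    stop_data("unknown tissue_label in manifest: ", bad_lab[1L])
  bad_qc <- setdiff(unique(man$qc_status), qc_statuses)
  if (length(bad_qc))
    stop_data("unknown qc_status in manifest: ", bad_qc[1L])
  spectra <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(spectra_dir, man$file[i])
    if (!file.exists(f))
      stop_data("spectrum file missing for ", man$spectrum_id[i], ": ", f)
    spectra[[i]] <- read_spectrum(
      f,
      spectrum_id = man$spectrum_id[i], patient_id = man$patient_id[i],
      sample_id = man$sample_id[i], tissue_label = man$tissue_label[i]
    )
  }
  oes_cohort(spectra,
             qc = data.frame(spectrum_id = man$spectrum_id,
                             status = man$qc_status,
                             stringsAsFactors = FALSE))
}

#' Write a cohort as manifest + one spectrum file per acquisition
#'
#' @param cohort an `oes_cohort`.
#' @param dir output directory (created if needed); spectra are written under
#'   `dir/spectra/`.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oes_cohort"))
  spectra_dir <- file.path(dir, "spectra")
  dir.create(spectra_dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$file <- file.path("spectra", paste0(man$spectrum_id, ".csv"))
  for (i in seq_along(cohort$spectra))
    write_spectrum(cohort$spectra[[i]], file.path(dir, man$file[i]))
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Keep only QC-passing spectra
#'
#' Partitions the cohort on QC status: every `ok` spectrum is retained, every
#' other spectrum is dropped, and the per-category exclusion counts are
#' reported via `message()`.
#'
#' @param cohort an `oes_cohort`.
#' @return the filtered `oes_cohort` (possibly with zero spectra, with a
#'   warning).
#' @export
apply_qc <- function(cohort) {
  stopifnot(inherits(cohort, "oes_cohort"))
  keep <- cohort$qc$status == "ok"
  excl <- table(cohort$qc$status[!keep])
  if (length(excl))
    message("apply_qc: excluded ", sum(!keep), " spectra (",
            paste(names(excl), excl, sep = "=", collapse = ", "),
            "), ", sum(keep), " retained")
  if (!any(keep)) {
    warning("apply_qc: no spectra passed QC", call. = FALSE)
    out <- cohort
    out$spectra <- cohort$spectra[keep]
    out$qc <- cohort$qc[keep, , drop = FALSE]
    out$patient_ids <- cohort$patient_ids[keep]
    return(out)
  }
  oes_cohort(cohort$spectra[keep],
             qc = cohort$qc[keep, , drop = FALSE])
}
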