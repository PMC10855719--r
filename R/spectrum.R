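#' Construct a single optical emission spectrum
#'
#' A spectrum is one acquisition: a strictly increasing wavelength grid (nm)
#' with non-negative detector counts, plus the acquisition metadata used
#' downstream (patient, sample, tissue label, integration time).
#'
#' @param wavelengths_nm numeric, strictly increasing, within \[150, 900\] nm.
#' @param intensities numeric, same length, finite and >= 0.
#' @param spectrum_id,patient_id,sample_id identifier strings.
#' @param tissue_label one of `"normal"`, `"abnormal"`, `"unlabeled"`.
#' @param integration_time_ms positive acquisition integration time
#'   (default 100 ms, the instrument setting emulated by the simulator).
#' @param sort_wavelengths if `TRUE` (default) unsorted input is sorted with a
#'   warning; duplicate wavelengths are always an error.
#' @return an object of class `oes_spectrum`.
#' @export
oes_spectrum <- function(wavelengths_nm, intensities,
                         spectrum_id = "spec1", patient_id = "P01",
                         sample_id = "S1",
                         tissue_label = c("unlabeled", "normal", "abnormal"),
                         integration_time_ms = 100,
                         sort_wavelengths = TRUE) {
  tissue_label <- match.arg(tissue_label)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) != length(intensities))
    stop_data("wavelength and intensity vectors differ in length (",
              length(wavelengths_nm), " vs ", length(intensities), ")")
  if (length(wavelengths_nm) == 0L)
    stop_data("empty spectrum")
  if (anyNA(wavelengths_nm) || any(!is.finite(wavelengths_nm)))
    stop_data("non-finite wavelengths")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop_data("non-finite intensities")
  if (any(intensities < 0))
    stop_data("negative intensities (first at row ",
              which(intensities < 0)[1L], ")")
  if (min(wavelengths_nm) < 150 || max(wavelengths_nm) > 900)
    stop_data("wavelengths outside [150, 900] nm")
  if (anyDuplicated(wavelengths_nm))
    stop_data("duplicate wavelengths (first at row ",
              which(duplicated(wavelengths_nm))[1L], ")")
  if (is.unsorted(wavelengths_nm)) {
    if (!sort_wavelengths) stop_data("wavelengths not increasing")
    warning("unsorted wavelengths: sorting (Echelle orders may interleave)",
            call. = FALSE)
    o <- order(wavelengths_nm)
    wavelengths_nm <- wavelengths_nm[o]
    intensities <- intensities[o]
  }
  if (!(is.numeric(integration_time_ms) && length(integration_time_ms) == 1L &&
        integration_time_ms > 0))
    stop_data("integration_time_ms must be a positive scalar")
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      patient_id = as.character(patient_id),
      sample_id = as.character(sample_id),
      tissue_label = tissue_label,
      wavelengths_nm = wavelengths_nm,
      intensities = intensities,
      integration_time_ms = as.numeric(integration_time_ms)
    ),
    class = "oes_spectrum"
  )
}

#' @export
print.oes_spectrum <- function(x, ...) {
  cat(sprintf(
    "<oes_spectrum %s> patient %s sample %s [%s]\n  %d points, %.2f-%.2f nm, max %.4g counts\n",
    x$spectrum_id, x$patient_id, x$sample_id, x$tissue_label,
    length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
    max(x$intensities)
  ))
  invisible(x)
}

#' Read a spectrum from two-column delimited text
#'
#' The on-disk dialect is deliberately plain: a CSV with header
#' `wavelength_nm,intensity` and one file per spectrum. All acquisition
#' metadata lives in the cohort manifest and can be attached via the `...`
#' arguments.
#'
#' @param path file to read.
#' @param ... metadata passed on to [oes_spectrum()] (`spectrum_id`,
#'   `patient_id`, `sample_id`, `tissue_label`, `integration_time_ms`).
#' @return an `oes_spectrum`.
#' @export
read_spectrum <- function(path, ...) {
  if (!file.exists(path)) stop_data("spectrum file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, check.names = FALSE)
  if (ncol(raw) < 2L)
    stop_data("expected two columns (wavelength_nm, intensity) in ", path)
  wl <- suppressWarnings(as.numeric(raw[[1L]]))
  it <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(wl) | is.na(it))
  if (length(bad))
    stop_data("non-numeric value in ", path, " at data row ", bad[1L])
  neg <- which(it < 0)
  if (length(neg))
    stop_data("negative intensity in ", path, " at data row ", neg[1L])
  oes_spectrum(wl, it, ...)
}

#' Write a spectrum in the two-column dialect
#'
#' @param spectrum an `oes_spectrum`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "oes_spectrum"))
  df <- data.frame(
    wavelength_nm = format(spectrum$wavelengths_nm, digits = 15, trim = TRUE,
                           scientific = FALSE),
    intensity = format(spectrum$intensities, digits = 15, trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
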