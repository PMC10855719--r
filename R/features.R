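#' Detect peaks in a spectrum
#'
#' Local maxima (strictly greater than both neighbouring runs; plateaus
#' resolved to their leftmost point) whose SNR against a [local_baseline()]
#' evaluated at the apex is at least `min_snr`. Candidates too close to the
#' spectrum edge for a baseline estimate are dropped. With `min_snr = -Inf`
#' the SNR stage is skipped entirely and all local maxima are returned
#' (`snr = NA`).
#'
#' @param spectrum an `oes_spectrum`.
#' @param min_snr minimum SNR for a peak to be reported (default 20).
#' @param inner_hw,outer_hw baseline annulus half-widths (nm).
#' @return data frame of class `peak_detections`: `apex_idx`, `apex_nm`,
#'   `height`, `snr`, `matched_species`, `matched_wavelength_nm` (the last
#'   two `NA` until [match_lines()]).
#' @export
detect_peaks <- function(spectrum, min_snr = 20, inner_hw = 0.15,
                         outer_hw = 0.60) {
  stopifnot(inherits(spectrum, "oes_spectrum"))
  w <- spectrum$wavelengths_nm
  y <- spectrum$intensities
  apex <- local_max_idx(y)
  snr <- rep(NA_real_, length(apex))
  if (is.finite(min_snr) && length(apex)) {
    keep <- logical(length(apex))
    for (k in seq_along(apex)) {
      bl <- tryCatch(
        local_baseline(spectrum, w[apex[k]], inner_hw, outer_hw),
        error = function(e) NULL)
      if (is.null(bl)) next  # edge: no baseline, peak not assessable
      snr[k] <- (y[apex[k]] - bl$mu) / bl$sd
      keep[k] <- snr[k] >= min_snr
    }
    apex <- apex[keep]
    snr <- snr[keep]
  }
  structure(
    data.frame(apex_idx = apex, apex_nm = w[apex], height = y[apex],
               snr = snr,
               matched_species = rep(NA_character_, length(apex)),
               matched_wavelength_nm = rep(NA_real_, length(apex)),
               stringsAsFactors = FALSE),
    class = c("peak_detections", "data.frame")
  )
}

#' Match detected peaks to catalogue emission lines
#'
#' Greedy nearest-first assignment: peak/line pairs within tolerance are
#' considered in order of increasing wavelength difference (ties broken
#' toward the smaller catalogue wavelength, then the smaller apex), and each
#' peak and each line is used at most once — a partial injection.
#'
#' @param peaks output of [detect_peaks()].
#' @param catalogue a line catalogue.
#' @param tol_nm match tolerance: a scalar, a per-line vector, or `NULL` for
#'   the [match_tolerance()] defaults (0.05 nm atomic / 0.5 nm broad).
#' @return `peaks` with `matched_species` / `matched_wavelength_nm` filled
#'   for assigned peaks.
#' @export
match_lines <- function(peaks, catalogue, tol_nm = NULL) {
  catalogue <- validate_catalogue(catalogue)
  tol <- if (is.null(tol_nm)) match_tolerance(catalogue) else
    rep_len(tol_nm, nrow(catalogue))
  if (nrow(peaks) == 0L) return(peaks)
  cand <- NULL
  for (j in seq_len(nrow(catalogue))) {
    d <- abs(peaks$apex_nm - catalogue$wavelength_nm[j])
    hit <- which(d <= tol[j])
    if (length(hit))
      cand <- rbind(cand, data.frame(peak = hit, line = j, diff = d[hit]))
  }
  if (is.null(cand)) return(peaks)
  cand <- cand[order(cand$diff, catalogue$wavelength_nm[cand$line],
                     peaks$apex_nm[cand$peak]), , drop = FALSE]
  peak_used <- logical(nrow(peaks))
  line_used <- logical(nrow(catalogue))
  for (r in seq_len(nrow(cand))) {
    p <- cand$peak[r]; l <- cand$line[r]
    if (peak_used[p] || line_used[l]) next
    peak_used[p] <- TRUE; line_used[l] <- TRUE
    peaks$matched_species[p] <- catalogue$species[l]
    peaks$matched_wavelength_nm[p] <- catalogue$wavelength_nm[l]
  }
  peaks
}

## one line, one spectrum: is there a local-max apex within tol of the
## centre, and what is the line SNR against the masked local baseline?
detect_line <- function(spectrum, center_nm, tol, inner_hw, outer_hw,
                        exclude_nm) {
  w <- spectrum$wavelengths_nm
  idx <- idx_range(w, center_nm - tol, center_nm + tol)
  if (!length(idx)) return(list(has_apex = FALSE, snr = -Inf))
  lo <- max(1L, idx[1L] - 1L)
  hi <- min(length(w), idx[length(idx)] + 1L)
  apex <- local_max_idx(spectrum$intensities[lo:hi]) + lo - 1L
  apex <- apex[apex %in% idx]
  if (!length(apex)) return(list(has_apex = FALSE, snr = -Inf))
  bl <- local_baseline(spectrum, center_nm, inner_hw, outer_hw, exclude_nm)
  list(has_apex = TRUE, snr = line_snr(spectrum, center_nm, bl))
}

#' Select the feature panel by SNR and occurrence rate
#'
#' A catalogue line enters the panel iff it is detected — a peak apex within
#' the match tolerance of the line centre whose SNR (strictly) exceeds
#' `min_snr` — in at least `min_occurrence` of the QC-passing spectra
#' (boundary inclusive: exactly 5% is retained). Baseline flanks mask all
#' other catalogue lines.
#'
#' @param cohort a QC-filtered `oes_cohort`.
#' @param catalogue a line catalogue.
#' @param min_snr detection SNR threshold (strict `>`, default 20).
#' @param min_occurrence minimum detection fraction in `(0, 1]`
#'   (default 0.05).
#' @param inner_hw,outer_hw baseline annulus half-widths for narrow lines;
#'   scaled by `broad_scale` for broad entries.
#' @param broad_scale annulus scale factor for broad lines (default 4).
#' @param tol_nm,tol_broad_nm match tolerances (see [match_tolerance()]).
#' @param integration_halfwidth_sigmas feature integration half-width in
#'   units of the line's profile sigma (default 3).
#' @return data frame of class `feature_panel`, ordered by wavelength:
#'   `species`, `wavelength_nm`, `profile_sigma_nm`, `broad`,
#'   `integration_halfwidth_nm`, `occurrence_rate`.
#' @export
select_panel <- function(cohort, catalogue = default_line_catalogue(),
                         min_snr = 20, min_occurrence = 0.05,
                         inner_hw = 0.15, outer_hw = 0.60, broad_scale = 4,
                         tol_nm = 0.05, tol_broad_nm = 0.5,
                         integration_halfwidth_sigmas = 3) {
  stopifnot(inherits(cohort, "oes_cohort"))
  if (length(cohort$spectra) == 0L) stop_analysis("empty cohort")
  if (!(min_occurrence > 0 && min_occurrence <= 1))
    stop_config("min_occurrence must be in (0, 1]")
  catalogue <- validate_catalogue(catalogue)
  catalogue <- catalogue[order(catalogue$wavelength_nm), , drop = FALSE]
  tol <- match_tolerance(catalogue, tol_nm, tol_broad_nm)
  excl <- line_exclusions(catalogue, tol)
  scale <- ifelse(catalogue$broad, broad_scale, 1)
  n_spec <- length(cohort$spectra)
  rate <- numeric(nrow(catalogue))
  for (l in seq_len(nrow(catalogue))) {
    det <- 0L
    for (sp in cohort$spectra) {
      d <- detect_line(sp, catalogue$wavelength_nm[l], tol[l],
                       inner_hw * scale[l], outer_hw * scale[l], excl[[l]])
      if (d$has_apex && d$snr > min_snr) det <- det + 1L
    }
    rate[l] <- det / n_spec
  }
  keep <- rate >= min_occurrence
  panel <- data.frame(
    species = catalogue$species[keep],
    wavelength_nm = catalogue$wavelength_nm[keep],
    profile_sigma_nm = catalogue$profile_sigma_nm[keep],
    broad = catalogue$broad[keep],
    integration_halfwidth_nm =
      integration_halfwidth_sigmas * catalogue$profile_sigma_nm[keep],
    occurrence_rate = rate[keep],
    stringsAsFactors = FALSE
  )
  class(panel) <- c("feature_panel", "data.frame")
  panel
}

#' Integrate a normalized spectrum around one panel line
#'
#' Trapezoidal integral of the (total-intensity normalized) spectrum over
#' `[center - w, center + w]`, minus the trapezoidal integral of the local
#' baseline mean over the same window, floored at zero.
#'
#' @param spectrum a normalized `oes_spectrum`.
#' @param center_nm line centre (nm).
#' @param halfwidth_nm integration half-width `w` (nm).
#' @param baseline a `baseline_estimate` on the normalized spectrum; computed
#'   with the given annuli if `NULL`.
#' @param inner_hw,outer_hw,exclude_nm passed to [local_baseline()] when
#'   `baseline` is `NULL`.
#' @return the integrated, baseline-subtracted feature value (>= 0).
#' @export
integrate_feature <- function(spectrum, center_nm, halfwidth_nm,
                              baseline = NULL, inner_hw = 0.15,
                              outer_hw = 0.60, exclude_nm = NULL) {
  stopifnot(inherits(spectrum, "oes_spectrum"))
  w <- spectrum$wavelengths_nm
  if (center_nm - halfwidth_nm < w[1L] ||
      center_nm + halfwidth_nm > w[length(w)])
    stop_analysis("integration window around ", center_nm,
                  " nm exceeds spectrum range")
  if (is.null(baseline))
    baseline <- local_baseline(spectrum, center_nm, inner_hw, outer_hw,
                               exclude_nm)
  idx <- idx_range(w, center_nm - halfwidth_nm, center_nm + halfwidth_nm)
  if (length(idx) < 2L) return(0)
  x <- w[idx]
  area <- trapz(x, spectrum$intensities[idx])
  base_area <- baseline$mu * (x[length(x)] - x[1L])
  max(0, area - base_area)
}

#' Build the spectra-by-features matrix
#'
#' One row per QC-passing spectrum in cohort order; each spectrum is
#' normalized to total intensity, then integrated around every panel line
#' (baseline-subtracted, floored at zero — undetected lines therefore yield
#' a defined value, not a missing one). Labels and patient ids are carried
#' through.
#'
#' @param cohort an `oes_cohort` (non-`ok` spectra are dropped).
#' @param panel a `feature_panel` from [select_panel()].
#' @param inner_hw,outer_hw,broad_scale baseline annulus parameters, as in
#'   [select_panel()].
#' @return object of class `feature_matrix`: list with `X` (numeric matrix,
#'   columns named `species_wavelength`), `labels` (factor
#'   normal/abnormal), `patient_ids`, `spectrum_ids`, `panel`.
#' @export
build_matrix <- function(cohort, panel, inner_hw = 0.15, outer_hw = 0.60,
                         broad_scale = 4) {
  stopifnot(inherits(cohort, "oes_cohort"))
  if (nrow(panel) == 0L) stop_analysis("empty feature panel")
  keep <- cohort$qc$status == "ok"
  spectra <- cohort$spectra[keep]
  if (!length(spectra)) stop_analysis("no QC-passing spectra")
  ## mask all other panel lines out of each line's baseline flanks
  hw <- pmax(3 * panel$profile_sigma_nm, panel$integration_halfwidth_nm)
  iv <- cbind(panel$wavelength_nm - hw, panel$wavelength_nm + hw)
  excl <- lapply(seq_len(nrow(panel)),
                 function(i) iv[-i, , drop = FALSE])
  scale <- ifelse(panel$broad, broad_scale, 1)
  X <- matrix(0, nrow = length(spectra), ncol = nrow(panel),
              dimnames = list(names(spectra),
                              paste0(panel$species, "_",
                                     panel$wavelength_nm)))
  for (i in seq_along(spectra)) {
    sp <- normalize_total(spectra[[i]])
    for (l in seq_len(nrow(panel))) {
      bl <- local_baseline(sp, panel$wavelength_nm[l],
                           inner_hw * scale[l], outer_hw * scale[l],
                           excl[[l]])
      X[i, l] <- integrate_feature(sp, panel$wavelength_nm[l],
                                   panel$integration_halfwidth_nm[l],
                                   baseline = bl)
    }
  }
  structure(
    list(
      X = X,
      labels = factor(vapply(spectra, `[[`, character(1L), "tissue_label"),
                      levels = c("normal", "abnormal")),
      patient_ids = unname(vapply(spectra, `[[`, character(1L),
                                  "patient_id")),
      spectrum_ids = names(spectra),
      panel = panel
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d spectra x %d features, %d patients (%s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$patient_ids)),
              paste(levels(x$labels), table(x$labels), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Two-class separability score per feature
#'
#' Absolute standardized mean difference
#' `|mean_abnormal - mean_normal| / pooled SD` per panel line, sorted
#' descending. A zero mean difference scores 0 regardless of the pooled SD;
#' disjoint class supports with zero pooled SD score `Inf`.
#'
#' @param fm a `feature_matrix` containing both classes.
#' @return data frame `species`, `wavelength_nm`, `score`, sorted by
#'   decreasing score.
#' @export
feature_scores <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  g <- fm$labels
  if (nlevels(droplevels(g)) < 2L)
    stop_analysis("feature scores need both tissue classes")
  a <- fm$X[g == "abnormal", , drop = FALSE]
  n <- fm$X[g == "normal", , drop = FALSE]
  d <- abs(colMeans(a) - colMeans(n))
  va <- apply(a, 2L, stats::var)
  vn <- apply(n, 2L, stats::var)
  psd <- sqrt(((nrow(a) - 1L) * va + (nrow(n) - 1L) * vn) /
                (nrow(a) + nrow(n) - 2L))
  score <- ifelse(d == 0, 0, d / psd)
  out <- data.frame(species = fm$panel$species,
                    wavelength_nm = fm$panel$wavelength_nm,
                    score = score, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
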