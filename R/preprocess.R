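#' Local baseline around an emission line
#'
#' Operationalizes the "surrounding baseline" of a line as two flanking
#' annuli `[center - outer, center - inner]` and `[center + inner,
#' center + outer]`; `mu` and `sd` are the mean and population SD of the
#' pooled flank intensities. Grid points falling into `exclude_nm` intervals
#' (typically other catalogue lines, see [line_exclusions()]) are dropped
#' from the flanks before estimation.
#'
#' @param spectrum an `oes_spectrum`.
#' @param center_nm line centre, nm.
#' @param inner_hw,outer_hw annulus half-widths, nm (defaults 0.15 / 0.60;
#'   callers scale both by `broad_scale` for broad lines).
#' @param exclude_nm optional 2-column matrix of wavelength intervals to
#'   exclude from the flanks.
#' @return list of class `baseline_estimate`: `center_nm`, `mu`, `sd`,
#'   `window_nm = c(inner_hw, outer_hw)`, `n_points`, `sd_floored`.
#'   A constant flank (SD 0) is replaced by a machine-epsilon-scaled floor
#'   with a warning; fewer than 10 points in either flank is an error.
#' @export
local_baseline <- function(spectrum, center_nm, inner_hw = 0.15,
                           outer_hw = 0.60, exclude_nm = NULL) {
  stopifnot(inherits(spectrum, "oes_spectrum"), inner_hw < outer_hw,
            inner_hw > 0)
  w <- spectrum$wavelengths_nm
  left <- idx_range(w, center_nm - outer_hw, center_nm - inner_hw)
  right <- idx_range(w, center_nm + inner_hw, center_nm + outer_hw)
  if (!is.null(exclude_nm) && length(exclude_nm)) {
    exclude_nm <- matrix(exclude_nm, ncol = 2L)
    for (r in seq_len(nrow(exclude_nm))) {
      drop <- idx_range(w, exclude_nm[r, 1L], exclude_nm[r, 2L])
      if (length(drop)) {
        left <- setdiff(left, drop)
        right <- setdiff(right, drop)
      }
    }
  }
  if (length(left) < 10L || length(right) < 10L)
    stop_analysis(sprintf(
      "too few baseline points around %.3f nm (left %d, right %d; >= 10 each required)",
      center_nm, length(left), length(right)))
  vals <- spectrum$intensities[c(left, right)]
  mu <- mean(vals)
  n <- length(vals)
  sdev <- sqrt(sum((vals - mu)^2) / n)  # population SD: fixed convention
  floored <- FALSE
  if (sdev == 0) {
    sdev <- sqrt(.Machine$double.eps) * max(1, abs(mu))
    floored <- TRUE
    warning(sprintf("constant baseline around %.3f nm: SD floored", center_nm),
            call. = FALSE)
  }
  structure(list(center_nm = center_nm, mu = mu, sd = sdev,
                 window_nm = c(inner = inner_hw, outer = outer_hw),
                 n_points = n, sd_floored = floored),
            class = "baseline_estimate")
}

#' Signal-to-noise ratio of a line
#'
#' `(peak_height - mu) / sd`, with `peak_height` the maximum intensity within
#' `+/- inner_hw` of the centre and `mu`, `sd` from a [local_baseline()].
#' Invariant under global rescaling of the spectrum.
#'
#' @param spectrum an `oes_spectrum`.
#' @param center_nm line centre, nm.
#' @param baseline a `baseline_estimate` (default: computed at `center_nm`).
#' @param inner_hw half-width of the peak search window (defaults to the
#'   baseline's inner half-width).
#' @return SNR, a dimensionless real.
#' @export
line_snr <- function(spectrum, center_nm, baseline = NULL, inner_hw = NULL) {
  stopifnot(inherits(spectrum, "oes_spectrum"))
  if (is.null(baseline))
    baseline <- local_baseline(spectrum, center_nm,
                               inner_hw = inner_hw %||% 0.15)
  inner_hw <- inner_hw %||% unname(baseline$window_nm["inner"])
  w <- spectrum$wavelengths_nm
  if (center_nm < w[1L] || center_nm > w[length(w)])
    stop_analysis("line centre ", center_nm, " nm outside spectrum range")
  core <- idx_range(w, center_nm - inner_hw, center_nm + inner_hw)
  if (!length(core))
    stop_analysis("no grid points within ", inner_hw, " nm of ", center_nm)
  (max(spectrum$intensities[core]) - baseline$mu) / baseline$sd
}

#' Carbon-line quality gate
#'
#' Spectra whose carbon emission line (247.856 nm) has an SNR below
#' `snr_min` times the SD of the surrounding baseline are unusable (too
#' little tissue material in the spark plasma) and are excluded. Exclusion is
#' strictly below the threshold: a spectrum at exactly `snr_min` is kept.
#' The gate runs on raw counts before normalization; the decision is
#' scale-invariant, so the order is immaterial. The neighbouring Fe line at
#' 248.327 nm is excluded from the baseline flanks by default.
#'
#' @param spectrum an `oes_spectrum` covering the carbon line.
#' @param snr_min gate threshold (default 20).
#' @param carbon_nm carbon line centre (default 247.856 nm).
#' @param inner_hw,outer_hw baseline annulus half-widths.
#' @param exclude_nm intervals excluded from the baseline flanks; default
#'   masks the Fe 248.327 nm line.
#' @return `TRUE` (keep) iff the carbon SNR is `>= snr_min`.
#' @export
carbon_gate <- function(spectrum, snr_min = 20, carbon_nm = 247.856,
                        inner_hw = 0.15, outer_hw = 0.60,
                        exclude_nm = cbind(248.327 - 0.1, 248.327 + 0.1)) {
  stopifnot(inherits(spectrum, "oes_spectrum"))
  w <- spectrum$wavelengths_nm
  if (w[1L] > carbon_nm - outer_hw || w[length(w)] < carbon_nm + outer_hw)
    stop_data("spectrum ", spectrum$spectrum_id,
              " does not cover the carbon line at ", carbon_nm, " nm")
  bl <- local_baseline(spectrum, carbon_nm, inner_hw, outer_hw,
                       exclude_nm = exclude_nm)
  line_snr(spectrum, carbon_nm, bl) >= snr_min
}

#' Normalize a spectrum to its total intensity
#'
#' Divides all intensities by their sum, so the spectrum sums to one and
#' global multiplicative factors (spark strength, coupling efficiency)
#' cancel. Idempotent up to floating point and scale-invariant.
#'
#' @param spectrum an `oes_spectrum` with positive total intensity.
#' @return the normalized `oes_spectrum`.
#' @export
normalize_total <- function(spectrum) {
  stopifnot(inherits(spectrum, "oes_spectrum"))
  total <- sum(spectrum$intensities)
  if (total <= 0)
    stop_data("cannot normalize spectrum ", spectrum$spectrum_id,
              ": total intensity is ", total)
  spectrum$intensities <- spectrum$intensities / total
  spectrum
}
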