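#' Default emission-line catalogue for breast-tissue spark spectra
#'
#' The 16 atomic emission lines reliably observed in electrosurgical spark
#' spectra of human breast tissue — P 213.618; Zn 213.855, 214.914;
#' C 247.856; Fe 248.327; Mg 279.522, 279.805, 280.270, 285.213;
#' Ca 393.366, 396.847, 422.673, 435.838; Na 588.995; K 766.490,
#' 769.896 nm — plus the molecular C2 Swan band head at 516.490 nm, which
#' marks fatty (normal) tissue. Entries are ordered by wavelength.
#'
#' `base_amplitude` is the expected peak amplitude (detector counts) in
#' normal tissue under the synthetic generator; `abnormal_multiplier` is the
#' fold-change of that amplitude in abnormal tissue. Defaults encode the
#' observed tissue contrasts: Mg, Zn, P and K markedly higher in abnormal
#' tissue, C2 higher in normal (multiplier < 1), Ca nearly equal, and the
#' matrix lines C, Fe and Na tissue-neutral. The Na line and the C2 band are
#' modelled as single broad Gaussians (`broad = TRUE`), the atomic lines as
#' narrow ones.
#'
#' @return data frame with columns `species`, `wavelength_nm`,
#'   `profile_sigma_nm`, `base_amplitude`, `abnormal_multiplier`, `broad`.
#' @export
default_line_catalogue <- function() {
  cat <- data.frame(
    species = c("P", "Zn", "Zn", "C", "Fe",
                "Mg", "Mg", "Mg", "Mg",
                "Ca", "Ca", "Ca", "Ca",
                "C2", "Na", "K", "K"),
    wavelength_nm = c(213.618, 213.855, 214.914, 247.856, 248.327,
                      279.522, 279.805, 280.270, 285.213,
                      393.366, 396.847, 422.673, 435.838,
                      516.490, 588.995, 766.490, 769.896),
    profile_sigma_nm = c(rep(0.015, 13), 0.35, 0.30, 0.015, 0.015),
    base_amplitude = c(600, 600, 500, 4000, 300,
                       1600, 800, 1200, 1000,
                       3000, 2400, 1200, 600,
                       1400, 2000, 1800, 1200),
    abnormal_multiplier = c(2.5, 2.5, 2.5, 1.0, 1.0,
                            3.0, 3.0, 3.0, 3.0,
                            1.1, 1.1, 1.1, 1.1,
                            0.5, 1.0, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
  cat$broad <- cat$profile_sigma_nm > 0.1
  cat[order(cat$wavelength_nm), , drop = FALSE]
}

#' Validate a line catalogue data frame
#' @keywords internal
validate_catalogue <- function(catalogue) {
  need <- c("species", "wavelength_nm", "profile_sigma_nm",
            "base_amplitude", "abnormal_multiplier")
  miss <- setdiff(need, names(catalogue))
  if (length(miss))
    stop_config("catalogue missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(catalogue) == 0L) stop_config("empty catalogue")
  with(catalogue, {
    if (any(profile_sigma_nm <= 0) || any(base_amplitude <= 0) ||
        any(abnormal_multiplier <= 0) || any(wavelength_nm <= 0))
      stop_config("catalogue entries must be positive")
  })
  if (is.null(catalogue$broad))
    catalogue$broad <- catalogue$profile_sigma_nm > 0.1
  catalogue
}

#' Per-line wavelength match tolerance
#'
#' Narrow atomic lines use a tight tolerance (default 0.05 nm, well under
#' half the 0.283 nm Mg 279.522/279.805 doublet gap that the spectrometer
#' resolves); broad entries (Na, C2) use a wide one (default 0.5 nm).
#'
#' @param catalogue a line catalogue.
#' @param tol_nm,tol_broad_nm tolerances for narrow/broad lines.
#' @return numeric vector, one tolerance per catalogue row.
#' @export
match_tolerance <- function(catalogue, tol_nm = 0.05, tol_broad_nm = 0.5) {
  catalogue <- validate_catalogue(catalogue)
  ifelse(catalogue$broad, tol_broad_nm, tol_nm)
}

#' Flank-exclusion intervals for each catalogue line
#'
#' When estimating the local baseline of line `i`, grid points belonging to
#' any *other* catalogue line must not enter the flanking annuli (blended
#' neighbours such as the Mg triplet or C/Fe would otherwise inflate the
#' baseline SD). Each line contributes the interval
#' `wavelength ± max(3 sigma, tolerance)`.
#'
#' @param catalogue a line catalogue.
#' @param tol per-line tolerances from [match_tolerance()].
#' @return list (one element per line) of 2-column matrices of intervals to
#'   exclude for that line.
#' @keywords internal
line_exclusions <- function(catalogue, tol = match_tolerance(catalogue)) {
  hw <- pmax(3 * catalogue$profile_sigma_nm, tol)
  all_iv <- cbind(catalogue$wavelength_nm - hw, catalogue$wavelength_nm + hw)
  lapply(seq_len(nrow(catalogue)), function(i) all_iv[-i, , drop = FALSE])
}
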