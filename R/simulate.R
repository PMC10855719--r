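#' Per-patient spectrum counts of the default 18-patient cohort
#'
#' Numbers of evaluable spectra recorded per patient from normal and abnormal
#' tissue in the study cohort the generator emulates.
#'
#' @return data frame with columns `n_normal`, `n_abnormal`, one row per
#'   patient.
#' @export
default_patient_counts <- function() {
  data.frame(
    n_normal = c(37, 24, 20, 64, 56, 70, 14, 22, 17, 11, 21, 11, 25, 12,
                 11, 9, 27, 30),
    n_abnormal = c(39, 17, 7, 42, 3, 60, 2, 15, 59, 10, 75, 16, 65, 6,
                   2, 23, 36, 17)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' The generator draws, for each patient, a log-scale random effect shared by
#' all of that patient's spectra; per spectrum and per line an independent
#' log-scale jitter; and additive homoscedastic detector noise on a uniform
#' wavelength grid. Amplitude of line l in a spectrum of tissue t is
#' `base_amplitude_l * abnormal_multiplier_l^{[t = abnormal]} *
#' exp(patient_effect + jitter_l)`.
#'
#' @param n_patients number of patients (default 18).
#' @param per_patient_counts data frame with columns `n_normal`,
#'   `n_abnormal`, one row per patient (default [default_patient_counts()]).
#' @param sigma_patient SD of the per-patient log-amplitude random effect.
#' @param sigma_spectrum SD of the per-spectrum, per-line log-amplitude
#'   jitter.
#' @param baseline_level flat background level, detector counts.
#' @param noise_sd additive detector noise SD, counts.
#' @param grid_start_nm,grid_end_nm,grid_step_nm uniform wavelength grid
#'   (defaults 200, 800, 0.02 nm — 30,001 points).
#' @param qc_fail_fraction fraction of spectra flagged with a random
#'   acquisition QC failure (default 0.02, mirroring 20/992 exclusions).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 18L,
                          per_patient_counts = default_patient_counts(),
                          sigma_patient = 0.15,
                          sigma_spectrum = 0.2,
                          baseline_level = 30,
                          noise_sd = 5,
                          grid_start_nm = 200,
                          grid_end_nm = 800,
                          grid_step_nm = 0.02,
                          qc_fail_fraction = 0.02,
                          seed = 42L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    per_patient_counts = as.data.frame(per_patient_counts),
    sigma_patient = sigma_patient, sigma_spectrum = sigma_spectrum,
    baseline_level = baseline_level, noise_sd = noise_sd,
    grid_start_nm = grid_start_nm, grid_end_nm = grid_end_nm,
    grid_step_nm = grid_step_nm,
    qc_fail_fraction = qc_fail_fraction, seed = as.integer(seed)
  )
  if (cfg$n_patients < 1L) stop_config("n_patients must be >= 1")
  if (!all(c("n_normal", "n_abnormal") %in% names(cfg$per_patient_counts)))
    stop_config("per_patient_counts needs columns n_normal, n_abnormal")
  if (nrow(cfg$per_patient_counts) != cfg$n_patients)
    stop_config("per_patient_counts must have one row per patient (",
                nrow(cfg$per_patient_counts), " rows for ",
                cfg$n_patients, " patients)")
  if (cfg$sigma_patient < 0 || cfg$sigma_spectrum < 0 ||
      cfg$baseline_level < 0 || cfg$noise_sd < 0)
    stop_config("variance/level parameters must be non-negative")
  if (!(cfg$grid_start_nm < cfg$grid_end_nm) || cfg$grid_step_nm <= 0)
    stop_config("invalid wavelength grid")
  if (cfg$qc_fail_fraction < 0 || cfg$qc_fail_fraction >= 1)
    stop_config("qc_fail_fraction must be in [0, 1)")
  structure(cfg, class = "cohort_config")
}

#' Wavelength grid of a cohort configuration
#' @param config a `cohort_config`.
#' @return numeric vector of wavelengths (nm).
#' @export
config_grid <- function(config) {
  seq(config$grid_start_nm, config$grid_end_nm, by = config$grid_step_nm)
}

#' Simulate one spark emission spectrum
#'
#' Intensity on the grid is
#' `I(w) = baseline_level + sum_l A_l exp(-(w - w_l)^2 / (2 sigma_l^2)) + eps(w)`
#' with `A_l` as documented in [cohort_config()] and
#' `eps ~ Normal(0, noise_sd^2)`, truncated so that intensities stay >= 0.
#' Gaussian profiles are evaluated within +/- 8 sigma of each line centre.
#'
#' Draws from the current R RNG stream (jitter first, in catalogue order,
#' then noise); seed management belongs to the caller / [simulate_cohort()].
#'
#' @param catalogue line catalogue (see [default_line_catalogue()]).
#' @param tissue `"normal"` or `"abnormal"`.
#' @param patient_effect log-scale patient random effect (scalar).
#' @param config a `cohort_config`.
#' @param grid optional precomputed wavelength grid (shared across spectra to
#'   avoid duplicating memory).
#' @param ... metadata passed to [oes_spectrum()].
#' @return an `oes_spectrum`.
#' @export
simulate_spectrum <- function(catalogue, tissue = c("normal", "abnormal"),
                              patient_effect = 0, config = cohort_config(),
                              grid = NULL, ...) {
  tissue <- match.arg(tissue)
  catalogue <- validate_catalogue(catalogue)
  if (is.null(grid)) grid <- config_grid(config)
  n <- length(grid)
  step <- config$grid_step_nm
  intens <- rep(config$baseline_level, n)
  jitter <- if (config$sigma_spectrum > 0)
    stats::rnorm(nrow(catalogue), 0, config$sigma_spectrum) else
    numeric(nrow(catalogue))
  for (l in seq_len(nrow(catalogue))) {
    wl <- catalogue$wavelength_nm[l]
    sig <- catalogue$profile_sigma_nm[l]
    amp <- catalogue$base_amplitude[l] *
      (if (tissue == "abnormal") catalogue$abnormal_multiplier[l] else 1) *
      exp(patient_effect + jitter[l])
    lo <- findInterval(wl - 8 * sig, grid) + 1L
    hi <- findInterval(wl + 8 * sig, grid)
    if (hi < lo) next
    idx <- lo:hi
    intens[idx] <- intens[idx] + amp * exp(-(grid[idx] - wl)^2 / (2 * sig^2))
  }
  if (config$noise_sd > 0)
    intens <- intens + stats::rnorm(n, 0, config$noise_sd)
  intens <- pmax(intens, 0)
  oes_spectrum(grid, intens, tissue_label = tissue, ...)
}

#' Simulate a full synthetic cohort
#'
#' Patient i receives a single random effect `~ Normal(0, sigma_patient^2)`
#' shared across all of its spectra, then `per_patient_counts[i, ]` spectra
#' per tissue class; a `qc_fail_fraction` of spectra is flagged with a random
#' acquisition failure status. Fully reproducible from `config$seed` (the
#' caller's RNG state is left untouched).
#'
#' @param config a [cohort_config()].
#' @param catalogue a line catalogue (default [default_line_catalogue()]).
#' @return an `oes_cohort`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            catalogue = default_line_catalogue()) {
  stopifnot(inherits(config, "cohort_config"))
  catalogue <- validate_catalogue(catalogue)
  grid <- config_grid(config)
  fail_statuses <- c("instrument_contamination", "poor_spectral_quality",
                     "memory_error")
  fail_prob <- c(10, 9, 1) / 20  # observed exclusion mix
  withr::with_seed(config$seed, {
    spectra <- list()
    status <- character(0)
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%02d", i)
      pe <- if (config$sigma_patient > 0)
        stats::rnorm(1, 0, config$sigma_patient) else 0
      for (tissue in c("normal", "abnormal")) {
        n_t <- config$per_patient_counts[[
          if (tissue == "normal") "n_normal" else "n_abnormal"]][i]
        sid <- paste0("S", i, if (tissue == "normal") "N" else "A")
        for (k in seq_len(n_t)) {
          spec_id <- sprintf("%s_%s_%03d", pid,
                             if (tissue == "normal") "N" else "A", k)
          sp <- simulate_spectrum(catalogue, tissue, pe, config, grid,
                                  spectrum_id = spec_id, patient_id = pid,
                                  sample_id = sid)
          st <- if (config$qc_fail_fraction > 0 &&
                    stats::runif(1) < config$qc_fail_fraction)
            sample(fail_statuses, 1L, prob = fail_prob) else "ok"
          spectra[[spec_id]] <- sp
          status <- c(status, st)
        }
      }
    }
    oes_cohort(spectra,
               qc = data.frame(spectrum_id = names(spectra), status = status,
                               stringsAsFactors = FALSE))
  })
}
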