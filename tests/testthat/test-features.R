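gauss_spectrum <- function(centers, amps, sigma = 0.015, lo = 278, hi = 282,
                           step = 0.02, base = 2) {
  w <- seq(lo, hi, by = step)
  y <- rep(base, length(w))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(w - centers[i])^2 / (2 * sigma^2))
  oes_spectrum(w, y)
}

test_that("detect_peaks equals the brute-force neighbour-scan oracle", {
  withr::local_seed(42)
  for (k in 1:200) {
    n <- sample(8:512, 1)
    y <- sample(0:12, n, replace = TRUE)  # integer values force plateaus
    s <- oes_spectrum(seq(200, by = 0.1, length.out = n), y)
    got <- detect_peaks(s, min_snr = -Inf)
    expect_identical(got$apex_idx, brute_peaks(y))
  }
  # monotone spectrum has no peaks
  s <- oes_spectrum(seq(200, 210, 0.5), seq(1, 2, length.out = 21))
  expect_equal(nrow(detect_peaks(s, min_snr = -Inf)), 0L)
})

test_that("detect_peaks locates synthetic Gaussians with SNR filtering", {
  s1 <- gauss_spectrum(279.522, 500)
  pk <- suppressWarnings(detect_peaks(s1, min_snr = 20))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_nm,
               s1$wavelengths_nm[which.min(abs(s1$wavelengths_nm - 279.522))])

  s2 <- gauss_spectrum(c(279.0, 281.0), c(400, 300))
  pk2 <- suppressWarnings(detect_peaks(s2, min_snr = 20, outer_hw = 0.4))
  expect_equal(nrow(pk2), 2L)
  expect_true(!is.unsorted(pk2$apex_nm))
})

test_that("match_lines assigns nearest catalogue lines as a partial injection", {
  cat <- default_line_catalogue()
  peaks <- data.frame(
    apex_idx = 1:3, apex_nm = c(247.856, 248.327, 300.0),
    height = c(5, 4, 3), snr = c(50, 40, 30),
    matched_species = NA_character_, matched_wavelength_nm = NA_real_)
  m <- match_lines(peaks, cat, tol_nm = 0.05)
  expect_equal(m$matched_species, c("C", "Fe", NA))
  # injection property on random peak sets
  withr::local_seed(4)
  for (k in 1:25) {
    peaks <- data.frame(
      apex_idx = 1:40,
      apex_nm = runif(40, 210, 800),
      height = runif(40), snr = runif(40, 0, 100),
      matched_species = NA_character_, matched_wavelength_nm = NA_real_)
    m <- match_lines(peaks, cat)
    hit <- m$matched_wavelength_nm[!is.na(m$matched_wavelength_nm)]
    expect_false(anyDuplicated(hit) > 0)
    # every match is within its line's tolerance
    tol <- match_tolerance(cat)
    for (i in which(!is.na(m$matched_wavelength_nm))) {
      j <- match(m$matched_wavelength_nm[i], cat$wavelength_nm)
      expect_lte(abs(m$apex_nm[i] - m$matched_wavelength_nm[i]), tol[j])
    }
  }
})

test_that("select_panel applies the occurrence boundary inclusively", {
  # one-line catalogue; the line is present in exactly 5 of 100 spectra
  cat1 <- data.frame(species = "Mg", wavelength_nm = 279.522,
                     profile_sigma_nm = 0.015, base_amplitude = 500,
                     abnormal_multiplier = 3, broad = FALSE)
  w <- seq(278, 282, by = 0.02)
  make <- function(with_peak, id) {
    y <- rep(2, length(w))
    if (with_peak)
      y <- y + 500 * exp(-(w - 279.522)^2 / (2 * 0.015^2))
    oes_spectrum(w, y, spectrum_id = id,
                 patient_id = sprintf("P%02d", (match(id, ids) %% 4) + 1))
  }
  ids <- sprintf("s%03d", 1:100)
  spectra5 <- lapply(seq_along(ids), function(i) make(i <= 5, ids[i]))
  co5 <- oes_cohort(spectra5)
  panel5 <- suppressWarnings(select_panel(co5, cat1))
  expect_equal(nrow(panel5), 1L)          # 5% occurrence: retained
  expect_equal(panel5$occurrence_rate, 0.05)

  spectra4 <- lapply(seq_along(ids), function(i) make(i <= 4, ids[i]))
  panel4 <- suppressWarnings(select_panel(oes_cohort(spectra4), cat1))
  expect_equal(nrow(panel4), 0L)          # 4%: dropped

  expect_error(select_panel(oes_cohort(spectra5[0]), cat1))
})

test_that("select_panel keeps all 17 lines on a low-noise synthetic cohort", {
  co <- simulate_cohort(small_config(n_patients = 2L, n_normal = 4L,
                                     n_abnormal = 4L, noise_sd = 1,
                                     seed = 17L))
  panel <- select_panel(co)
  expect_equal(nrow(panel), 17L)
  expect_equal(panel$wavelength_nm, sort(panel$wavelength_nm))
  # monotone in min_occurrence: raising the threshold never adds lines
  p_low <- select_panel(co, min_occurrence = 0.05)
  p_hi <- select_panel(co, min_occurrence = 0.9)
  expect_true(all(p_hi$wavelength_nm %in% p_low$wavelength_nm))
})

test_that("integrate_feature matches the analytic Gaussian area", {
  # unit-area Gaussian on zero baseline, window +/- 4 sigma
  sigma <- 0.05
  w <- seq(516, 517, by = 0.002)
  y <- exp(-(w - 516.49)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  s <- oes_spectrum(w, y)
  bl0 <- structure(list(center_nm = 516.49, mu = 0, sd = 1,
                        window_nm = c(inner = 0.2, outer = 0.45),
                        n_points = 50L, sd_floored = FALSE),
                   class = "baseline_estimate")
  area <- integrate_feature(s, 516.49, 4 * sigma, baseline = bl0)
  analytic <- 2 * stats::pnorm(4) - 1      # mass within 4 sigma
  expect_equal(area, analytic, tolerance = 1e-3)

  # spectrum equal to its baseline everywhere -> 0
  s_flat <- oes_spectrum(w, rep(3, length(w)))
  expect_equal(suppressWarnings(
    integrate_feature(s_flat, 516.49, 0.2)), 0)

  # window exceeding the spectrum range -> error
  expect_error(integrate_feature(s, 516.95, 0.2, baseline = bl0),
               "exceeds spectrum range")
})

test_that("build_matrix yields finite non-negative rows in cohort order", {
  co <- simulate_cohort(small_config(n_patients = 3L, n_normal = 3L,
                                     n_abnormal = 3L, seed = 31L))
  fm <- small_matrix(co)
  expect_equal(dim(fm$X), c(18L, 17L))
  expect_true(all(is.finite(fm$X)) && all(fm$X >= 0))
  expect_identical(fm$spectrum_ids, names(co$spectra))
  expect_identical(fm$patient_ids,
                   unname(vapply(co$spectra, `[[`, character(1),
                                 "patient_id")))
})

test_that("features are invariant to global rescaling of raw spectra", {
  co <- simulate_cohort(small_config(n_patients = 2L, n_normal = 2L,
                                     n_abnormal = 2L, seed = 12L))
  panel <- select_panel(co)
  co_scaled <- co
  for (i in seq_along(co_scaled$spectra))
    co_scaled$spectra[[i]]$intensities <-
      co_scaled$spectra[[i]]$intensities * 251.7
  fm <- build_matrix(co, panel)
  fm_scaled <- build_matrix(co_scaled, panel)
  expect_equal(fm$X, fm_scaled$X, tolerance = 1e-10)
})

test_that("feature scores rank Mg far above Ca and handle degenerate input", {
  co <- simulate_cohort(small_config(seed = 23L))
  fm <- small_matrix(co)
  sc <- feature_scores(fm)
  mg <- sc$score[sc$wavelength_nm == 279.522]
  ca <- sc$score[sc$wavelength_nm == 393.366]
  expect_gt(mg, ca)

  # identical class distributions -> all scores 0
  fm0 <- fm
  half <- seq_len(nrow(fm0$X) / 2)
  fm0$X <- rbind(fm0$X[half, ], fm0$X[half, ])
  fm0$labels <- factor(rep(c("normal", "abnormal"), each = length(half)),
                       levels = c("normal", "abnormal"))
  fm0$patient_ids <- rep(fm0$patient_ids[half], 2)
  expect_true(all(feature_scores(fm0)$score == 0))

  fm1 <- fm
  fm1$labels <- factor(rep("normal", nrow(fm1$X)),
                       levels = c("normal", "abnormal"))
  expect_error(feature_scores(fm1), "both tissue classes")
})
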