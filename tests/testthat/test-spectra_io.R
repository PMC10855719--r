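test_that("spectrum constructor enforces the invariants", {
  s <- oes_spectrum(c(200.0, 200.02), c(10, 12))
  expect_s3_class(s, "oes_spectrum")
  expect_length(s$wavelengths_nm, 2L)

  expect_error(oes_spectrum(c(200, 201), c(10, -3)), "negative.*row 2")
  expect_error(oes_spectrum(c(200, 200), c(1, 2)), "duplicate")
  expect_error(oes_spectrum(c(100, 200), c(1, 2)), "\\[150, 900\\]")
  expect_error(oes_spectrum(c(200, 201), c(1, 2, 3)), "length")
  expect_error(oes_spectrum(c(200, 201), c(1, Inf)), "finite")
  expect_warning(s2 <- oes_spectrum(c(201, 200), c(5, 9)), "unsorted")
  expect_equal(s2$wavelengths_nm, c(200, 201))
  expect_equal(s2$intensities, c(9, 5))
})

test_that("read_spectrum rejects malformed files with the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,intensity", "200.0,10", "200.02,abc"), f)
  expect_error(read_spectrum(f), "non-numeric.*row 2")
  writeLines(c("wavelength_nm,intensity", "200.0,10", "200.02,-3"), f)
  expect_error(read_spectrum(f), "negative.*row 2")
  writeLines(c("wavelength_nm,intensity", "200.0,10", "200.02,12"), f)
  s <- read_spectrum(f, spectrum_id = "a", patient_id = "P", tissue_label = "normal")
  expect_equal(s$intensities, c(10, 12))
  expect_equal(s$tissue_label, "normal")
})

test_that("write/read round-trip is lossless to 1e-9 relative", {
  withr::local_seed(11)
  for (k in 1:20) {
    s <- random_spectrum(n = sample(16:200, 1), id = sprintf("rt%02d", k))
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectrum(s, f)
    s2 <- read_spectrum(f, spectrum_id = s$spectrum_id)
    expect_equal(s2$wavelengths_nm, s$wavelengths_nm, tolerance = 1e-9)
    expect_equal(s2$intensities, s$intensities, tolerance = 1e-9)
  }
})

test_that("cohort round-trips through manifest + spectrum files", {
  withr::local_seed(3)
  spectra <- list(
    oes_spectrum(200 + 1:20 * 0.5, runif(20, 1, 5), spectrum_id = "a1",
                 patient_id = "P01", sample_id = "S1",
                 tissue_label = "normal"),
    oes_spectrum(200 + 1:20 * 0.5, runif(20, 1, 5), spectrum_id = "a2",
                 patient_id = "P01", sample_id = "S2",
                 tissue_label = "abnormal"),
    oes_spectrum(200 + 1:20 * 0.5, runif(20, 1, 5), spectrum_id = "b1",
                 patient_id = "P02", sample_id = "S3",
                 tissue_label = "normal"),
    oes_spectrum(200 + 1:20 * 0.5, runif(20, 1, 5), spectrum_id = "b2",
                 patient_id = "P02", sample_id = "S4",
                 tissue_label = "abnormal")
  )
  qc <- data.frame(spectrum_id = c("a1", "a2", "b1", "b2"),
                   status = c("ok", "ok", "memory_error", "ok"))
  co <- oes_cohort(spectra, qc)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(file.path(dir, "manifest.csv"), dir)
  expect_length(co2$spectra, 4L)
  expect_equal(sort(unique(co2$patient_ids)), c("P01", "P02"))
  expect_equal(co2$qc$status[co2$qc$spectrum_id == "b1"], "memory_error")
  expect_equal(co2$spectra[["a1"]]$intensities,
               spectra[[1]]$intensities, tolerance = 1e-9)
  # flagged spectrum is loaded but excluded downstream
  kept <- suppressMessages(apply_qc(co2))
  expect_false("b1" %in% names(kept$spectra))
  expect_length(kept$spectra, 3L)
})

test_that("read_cohort rejects broken manifests", {
  dir <- withr::local_tempdir()
  s <- oes_spectrum(c(200, 201), c(1, 2), spectrum_id = "x1")
  write_spectrum(s, file.path(dir, "x1.csv"))
  man <- data.frame(spectrum_id = "x1", patient_id = "P01", sample_id = "S1",
                    tissue_label = "normal", qc_status = "ok",
                    file = "x1.csv")
  path <- file.path(dir, "manifest.csv")

  bad <- man; bad$file <- "absent.csv"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path, dir), "missing for x1")

  bad <- man; bad$tissue_label <- "weird"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path, dir), "tissue_label")

  bad <- rbind(man, man)
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path, dir), "duplicate spectrum_id")
})

test_that("apply_qc is a partition on QC status", {
  # the historical accounting: 992 recorded, 10 contamination + 9 poor
  # quality + 1 memory error flagged, 972 evaluable
  w <- c(200, 201, 202)
  spectra <- lapply(seq_len(992), function(i)
    oes_spectrum(w, c(1, 2, 1), spectrum_id = sprintf("s%03d", i),
                 patient_id = sprintf("P%02d", (i %% 18) + 1)))
  status <- c(rep("instrument_contamination", 10),
              rep("poor_spectral_quality", 9), "memory_error",
              rep("ok", 972))
  co <- oes_cohort(spectra, data.frame(
    spectrum_id = sprintf("s%03d", seq_len(992)), status = status))
  kept <- suppressMessages(apply_qc(co))
  expect_length(kept$spectra, 972L)
  expect_true(all(kept$qc$status == "ok"))
  # partition: kept = ok, dropped = everything else
  expect_setequal(names(kept$spectra),
                  co$qc$spectrum_id[co$qc$status == "ok"])

  # all ok -> identity
  all_ok <- oes_cohort(spectra[1:5])
  expect_equal(suppressMessages(apply_qc(all_ok))$qc, all_ok$qc)

  # all flagged -> empty cohort with warning
  all_bad <- oes_cohort(spectra[1:5], data.frame(
    spectrum_id = sprintf("s%03d", 1:5),
    status = rep("memory_error", 5)))
  expect_warning(empty <- suppressMessages(apply_qc(all_bad)), "no spectra")
  expect_length(empty$spectra, 0L)
})
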