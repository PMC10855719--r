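# small deterministic feature_matrix builder for classifier tests
toy_matrix <- function(n_per_patient = 6L, n_patients = 4L, sep = 4,
                       seed = 1L, p = 2L) {
  withr::local_seed(seed)
  rows <- n_per_patient * n_patients
  X <- matrix(rnorm(rows * p), ncol = p)
  labels <- rep_len(c("normal", "abnormal"), rows)
  X[labels == "abnormal", ] <- X[labels == "abnormal", ] + sep
  structure(list(
    X = X,
    labels = factor(labels, levels = c("normal", "abnormal")),
    patient_ids = rep(sprintf("P%02d", seq_len(n_patients)),
                      each = n_per_patient),
    spectrum_ids = sprintf("s%03d", seq_len(rows)),
    panel = data.frame(species = paste0("F", seq_len(p)))
  ), class = "feature_matrix")
}

test_that("make_splits builds a leave-one-patient-out partition", {
  fm <- toy_matrix(n_patients = 5L)
  plan <- make_splits(fm)
  expect_length(plan, 5L)
  all_test <- integer(0)
  for (f in plan) {
    expect_true(all(fm$patient_ids[f$test_idx] == f$test_patient_id))
    expect_false(f$test_patient_id %in% fm$patient_ids[f$train_idx])
    expect_length(intersect(f$train_idx, f$test_idx), 0L)
    expect_setequal(c(f$train_idx, f$test_idx), seq_len(nrow(fm$X)))
    all_test <- c(all_test, f$test_idx)
  }
  expect_setequal(all_test, seq_len(nrow(fm$X)))   # partition
  expect_equal(anyDuplicated(all_test), 0L)        # each row exactly once

  fm1 <- fm
  fm1$patient_ids <- rep("P01", nrow(fm$X))
  expect_error(make_splits(fm1), ">= 2 patients")
})

test_that("svc training separates toy data and is deterministic", {
  fm <- toy_matrix(sep = 5)
  m <- svc_fit(fm$X, fm$labels)
  expect_equal(mean(predict(m, fm$X) == as.character(fm$labels)), 1)

  m2 <- svc_fit(fm$X, fm$labels)
  expect_identical(predict(m, fm$X), predict(m2, fm$X))

  expect_error(svc_fit(fm$X, rep("normal", nrow(fm$X))), "single class")
  expect_error(predict(m, fm$X[, 1, drop = FALSE]), "mismatch")
  expect_identical(predict(m, fm$X[0, , drop = FALSE]), character(0))
})

test_that("predictions are invariant to a constant shift of all features", {
  fm <- toy_matrix(sep = 3, seed = 9L)
  m1 <- svc_fit(fm$X, fm$labels)
  shift <- 113.7
  m2 <- svc_fit(fm$X + shift, fm$labels)
  probe <- fm$X[1:8, , drop = FALSE]
  expect_identical(predict(m1, probe), predict(m2, probe + shift))
})

test_that("label-permuted training yields chance held-out accuracy", {
  withr::local_seed(101)
  train_X <- matrix(rnorm(400), ncol = 2)
  train_y <- sample(rep(c("normal", "abnormal"), each = 100))
  test_X <- matrix(rnorm(400), ncol = 2)
  test_y <- rep(c("normal", "abnormal"), each = 100)
  m <- svc_fit(train_X, train_y)
  acc <- mean(predict(m, test_X) == test_y)
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / 200) + 0.05)
})

test_that("evaluate_confusion matches closed-form metric examples", {
  cc <- evaluate_confusion(rep(c("abnormal", "normal"), c(4, 5)),
                           rep(c("abnormal", "normal"), c(4, 5)))
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 4L, tn = 5L, fp = 0L, fn = 0L))

  cc2 <- evaluate_confusion(
    truth = c(rep("abnormal", 4), rep("normal", 5)),
    pred = c("abnormal", "abnormal", "abnormal", "normal",
             rep("normal", 5)))
  m <- confusion_metrics(cc2)
  expect_equal(unname(m), c(8 / 9, 0.75, 1.0, 1.0, 5 / 6))

  # degenerate: everything predicted abnormal, no abnormal truths
  cc3 <- evaluate_confusion(rep("normal", 6), rep("abnormal", 6))
  m3 <- confusion_metrics(cc3)
  expect_equal(unname(m3["ppv"]), 0)
  expect_equal(unname(m3["specificity"]), 0)
  expect_true(is.na(m3["sensitivity"]))

  expect_error(evaluate_confusion(c("normal", "odd"), c("normal", "normal")),
               "unknown label")
  expect_error(evaluate_confusion("normal", c("normal", "normal")),
               "lengths differ")
})

test_that("confusion counting matches a brute-force recount", {
  withr::local_seed(77)
  for (k in 1:1000) {
    n <- sample(1:100, 1)
    truth <- sample(c("normal", "abnormal"), n, replace = TRUE)
    pred <- sample(c("normal", "abnormal"), n, replace = TRUE)
    got <- evaluate_confusion(truth, pred)
    want <- brute_confusion(truth, pred)
    expect_identical(unclass(got)[c("tp", "fp", "tn", "fn")],
                     want[c("tp", "fp", "tn", "fn")])
    gm <- confusion_metrics(got)
    expect_equal(gm, want$metrics)
    expect_equal(got$tp + got$fp + got$tn + got$fn, n)
    defined <- gm[!is.na(gm)]
    expect_true(all(defined >= 0 & defined <= 1))
  }
})

test_that("run_lopo is perfect on separable data and means recompute", {
  fm <- toy_matrix(sep = 6, n_patients = 5L)
  rep_ <- suppressMessages(run_lopo(fm))
  expect_true(all(as.matrix(rep_$per_patient[-1]) == 1))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    expect_equal(unname(rep_$mean[m]),
                 mean(rep_$per_patient[[m]], na.rm = TRUE))
  expect_equal(sum(rep_$confusion$tp + rep_$confusion$fp +
                     rep_$confusion$tn + rep_$confusion$fn), nrow(fm$X))
})

test_that("patient-index features do not leak into LOPO folds", {
  # a feature equal to the patient index is useless under LOPO:
  # null-label accuracy stays at chance
  withr::local_seed(55)
  n_patients <- 6L
  per <- 20L
  fm <- toy_matrix(n_per_patient = per, n_patients = n_patients, sep = 0,
                   seed = 55L)
  fm$X <- cbind(fm$X, patient_index = rep(seq_len(n_patients), each = per))
  rep_ <- suppressMessages(run_lopo(fm))
  total <- sum(rep_$confusion$tp + rep_$confusion$tn)
  n <- nrow(fm$X)
  expect_lt(abs(total / n - 0.5), 1.96 * sqrt(0.25 / n) + 0.05)
})
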