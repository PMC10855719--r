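# Independent brute-force oracles. These deliberately re-derive results with
# naive scans so the package implementations are checked against a second,
# unrelated code path.

# peak positions by explicit neighbour scan: strictly above both neighbouring
# values; a plateau counts once, at its leftmost point
brute_peaks <- function(y) {
  n <- length(y)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# confusion counts and metrics by explicit per-element loop
brute_confusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "abnormal") {
      if (pred[i] == "abnormal") tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[i] == "abnormal") fp <- fp + 1L else tn <- tn + 1L
    }
  }
  div <- function(a, b) if (b == 0L) NA_real_ else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       metrics = c(accuracy = div(tp + tn, tp + fp + tn + fn),
                   sensitivity = div(tp, tp + fn),
                   specificity = div(tn, tn + fp),
                   ppv = div(tp, tp + fp),
                   npv = div(tn, tn + fn)))
}

# random valid spectrum for property tests
random_spectrum <- function(n = 128L, lo = 200, hi = 800, id = "r1") {
  w <- sort(runif(n, lo, hi))
  while (anyDuplicated(w)) w <- sort(runif(n, lo, hi))
  oes_spectrum(w, runif(n, 0, 100), spectrum_id = id)
}
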