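`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integration
#'
#' @param x ordered abscissae.
#' @param y ordinates, same length as `x`.
#' @return the trapezoid-rule integral of `y` over `x`.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

## index range of grid points with a <= w <= b (w sorted ascending);
## O(log n) via findInterval, used everywhere instead of logical masks
idx_range <- function(w, a, b) {
  lo <- findInterval(a, w, left.open = TRUE) + 1L
  hi <- findInterval(b, w)
  if (hi < lo) integer(0) else lo:hi
}

## Classed conditions so the CLI can map failures to exit codes
## (2 = config, 3 = data, 4 = analysis).
stop_config <- function(...) stop_classed("sparkspec_config_error", ...)
stop_data <- function(...) stop_classed("sparkspec_data_error", ...)
stop_analysis <- function(...) stop_classed("sparkspec_analysis_error", ...)

stop_classed <- function(class, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-2L))
  ))
}

#' Indices of local maxima with plateau handling
#'
#' A position is a peak when its value is strictly greater than the values of
#' both neighbouring runs; a plateau (run of equal values) is resolved to its
#' leftmost point. Endpoints are never peaks.
#'
#' @param y numeric vector.
#' @return integer indices of peak apices, ascending.
#' @keywords internal
local_max_idx <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(y)
  k <- length(r$lengths)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  is_peak <- c(FALSE, v[2:(k - 1L)] > v[1:(k - 2L)] & v[2:(k - 1L)] > v[3:k], FALSE)
  starts[is_peak]
}
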