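## squared Euclidean cross-distances, rows of A vs rows of B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

rbf_kernel <- function(A, B, gamma) exp(-gamma * cross_dist2(A, B))

#' Fit an RBF-kernel support-vector classifier
#'
#' Maximum-margin binary classifier on the feature rows: features are
#' centred and scaled on the training rows only (the transform is embedded
#' in the model), then a C-SVC with radial-basis kernel
#' `K(u, v) = exp(-gamma ||u - v||^2)` is trained by a deterministic SMO
#' solver. Positive class is `abnormal`.
#'
#' @param X numeric matrix, one row per training spectrum.
#' @param y labels: factor or character in `{normal, abnormal}` (both classes
#'   required).
#' @param cost soft-margin constant C (default 1).
#' @param gamma kernel scale; default `"scale"` = `1 / (p * mean variance)`
#'   of the standardized training features.
#' @param tol SMO KKT tolerance (default 1e-3).
#' @return object of class `oes_svc` implementing [predict.oes_svc()].
#' @export
svc_fit <- function(X, y, cost = 1, gamma = "scale", tol = 1e-3) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  bad <- setdiff(unique(y), c("normal", "abnormal"))
  if (length(bad)) stop_analysis("unknown label: ", bad[1L])
  if (length(unique(y)) < 2L)
    stop_analysis("training set contains a single class (", unique(y), ")")
  if (nrow(X) != length(y)) stop_analysis("rows of X and labels differ")
  yy <- ifelse(y == "abnormal", 1, -1)

  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")

  if (identical(gamma, "scale")) {
    mv <- mean(apply(Xs, 2L, stats::var))
    gamma <- 1 / (ncol(Xs) * if (mv > 0) mv else 1)
  }
  K <- rbf_kernel(Xs, Xs, gamma)
  fit <- smo_train(K, yy, C = cost, tol = tol)
  if (!fit$converged)
    warning("SMO did not fully converge within the iteration budget",
            call. = FALSE)
  sv <- fit$alpha > 1e-8
  structure(
    list(alpha_y = fit$alpha[sv] * yy[sv], b = fit$b,
         X_sv = Xs[sv, , drop = FALSE], gamma = gamma, cost = cost,
         center = center, scale = scl, n_features = ncol(Xs),
         n_sv = sum(sv)),
    class = "oes_svc"
  )
}

#' Predict tissue labels with a fitted SVC
#'
#' @param object an `oes_svc` from [svc_fit()].
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return character vector of `"normal"` / `"abnormal"`, one per row
#'   (decision value > 0 maps to `abnormal`).
#' @export
predict.oes_svc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(character(0))
  if (ncol(newdata) != object$n_features)
    stop_analysis("feature count mismatch: model has ", object$n_features,
                  ", data has ", ncol(newdata))
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  dec <- drop(rbf_kernel(Xs, object$X_sv, object$gamma) %*% object$alpha_y) +
    object$b
  ifelse(dec > 0, "abnormal", "normal")
}

#' @export
print.oes_svc <- function(x, ...) {
  cat(sprintf("<oes_svc> RBF C-SVC: %d SVs, %d features, C=%g, gamma=%.4g\n",
              x$n_sv, x$n_features, x$cost, x$gamma))
  invisible(x)
}
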