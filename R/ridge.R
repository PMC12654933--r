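#' Ridge regression with closed-form leave-one-out shrinkage selection
#'
#' Fits `targets ~ features` by L2-regularized least squares, choosing each
#' target's shrinkage from a grid by leave-one-out cross-validation. The
#' LOO errors are computed in closed form from one SVD of the feature
#' matrix via the hat-matrix identity `e_i = (y_i - yhat_i) / (1 - h_i)` —
#' no refitting loop — and equal the explicit n-refit leave-one-out errors
#' to numerical precision. Final weights are refit on all rows at the
#' chosen shrinkage.
#'
#' No intercept is fit: features and targets are expected to be centered
#' or z-scored beforehand (as [extract_gabor_features()] guarantees for
#' features).
#'
#' @param features Numeric matrix, `n` × `p` (`n >= 3`).
#' @param targets Numeric vector or `n` × `t` matrix of regression targets.
#' @param shrinkage Strictly increasing positive grid of ridge penalties;
#'   default 30 values log-spaced from 1e4 to 1e8.
#' @return An object of class `ridge_fit`: `weights` (`p` × `t`), `lambda`
#'   (chosen shrinkage per target), `loo` (`t` × grid mean squared LOO
#'   errors), `grid`. A [tidy()] method returns per-target summaries and
#'   `predict()` maps new feature rows to predictions.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' fit <- ridge_loocv(x, x[, 1] + rnorm(20, sd = .1), shrinkage = 10^seq(-2, 2))
#' fit$lambda
#' @export
ridge_loocv <- function(features, targets,
                        shrinkage = 10^seq(4, 8, length.out = 30)) {
  x <- as.matrix(features); y <- as.matrix(targets)
  n <- nrow(x)
  if (n < 3L) abort("need at least 3 rows for leave-one-out selection")
  if (nrow(y) != n) abort("features and targets must have equal row counts")
  if (length(shrinkage) < 1L || any(shrinkage <= 0)) abort("`shrinkage` must be positive")
  if (is.unsorted(shrinkage, strictly = TRUE)) abort("`shrinkage` must be strictly increasing")
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * 1e-12
  u <- sv$u[, pos, drop = FALSE]; d2 <- sv$d[pos]^2
  uty <- crossprod(u, y)
  n_t <- ncol(y)
  loo <- matrix(NA_real_, n_t, length(shrinkage))
  for (j in seq_along(shrinkage)) {
    shr <- d2 / (d2 + shrinkage[j])
    fitted <- u %*% (shr * uty)
    h <- as.vector(u^2 %*% shr)
    loo[, j] <- colMeans(((y - fitted) / (1 - h))^2)
  }
  best <- apply(loo, 1L, which.min)
  weights <- matrix(NA_real_, ncol(x), n_t)
  v <- sv$v[, pos, drop = FALSE]
  for (j in unique(best)) {
    sel <- which(best == j)
    coefs <- sv$d[pos] / (d2 + shrinkage[j])
    weights[, sel] <- v %*% (coefs * uty[, sel, drop = FALSE])
  }
  structure(
    list(weights = weights, lambda = shrinkage[best],
         loo = loo, grid = shrinkage),
    class = "ridge_fit"
  )
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> %d feature(s), %d target(s); shrinkage grid %g..%g\n",
              nrow(x$weights), ncol(x$weights), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @rdname ridge_loocv
#' @param object A `ridge_fit`.
#' @param newdata Numeric matrix of new feature rows.
#' @param ... Unused.
#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$weights
}

#' @rdname ridge_loocv
#' @param x A `ridge_fit`.
#' @export
tidy.ridge_fit <- function(x, ...) {
  tibble(target = seq_along(x$lambda), lambda = x$lambda,
         loo_error = x$loo[cbind(seq_along(x$lambda),
                                 match(x$lambda, x$grid))])
}
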