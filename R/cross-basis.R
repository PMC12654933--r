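#' Learn an aligned latent basis from a training split
#'
#' Centers the two training matrices by their own column means and takes the
#' singular value decomposition of the cross-covariance
#' `C = (1/n) t(A_c) %*% B_c`. The left/right singular vectors `U` and `V`
#' are orthonormal rotations into a shared latent space (the Procrustes /
#' PLS-SVD alignment used by hyperalignment), and the singular values are
#' the training-split variance shared along each latent dimension, sorted
#' nonincreasing. Components beyond `K = min(d_X, d_Y, n_train - 1)` are
#' discarded (centering removes one degree of freedom).
#'
#' Sign convention: training singular values are kept nonnegative and,
#' within each pair `(u_k, v_k)`, the largest-magnitude element of `u_k` is
#' made positive. Signs cancel in all spectra; the convention only
#' stabilizes regression tests. Ordering among exactly tied singular values
#' is implementation-defined.
#'
#' @param train_a,train_b Numeric matrices (or [response_set()]s) with the
#'   same number of rows (`n_train >= 2`); rows are stimuli, columns
#'   channels.
#' @return An object of class `cross_basis`: list with orthonormal `u`
#'   (`d_X` × K), `v` (`d_Y` × K), nonincreasing `sigma_train` (length K),
#'   training means `mean_a`, `mean_b`, `n_train` and `k`.
#' @examples
#' a <- matrix(rnorm(36), 12, 3); b <- matrix(rnorm(48), 12, 4)
#' basis <- fit_cross_basis(a, b)
#' basis$sigma_train
#' @export
fit_cross_basis <- function(train_a, train_b) {
  a <- as_values(train_a); b <- as_values(train_b)
  n <- nrow(a)
  if (nrow(b) != n) abort("training matrices must have equal row counts")
  if (n < 2L) abort("need at least 2 training rows")
  ma <- colMeans(a); mb <- colMeans(b)
  cxy <- crossprod(center_cols(a, ma), center_cols(b, mb)) / n
  k <- min(ncol(a), ncol(b), n - 1L)
  sv <- svd(cxy, nu = k, nv = k)
  u <- sv$u; v <- sv$v
  ## fix signs jointly per pair: largest-|u_k| element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  structure(
    list(u = u, v = v, sigma_train = sv$d[seq_len(k)],
         mean_a = ma, mean_b = mb, n_train = n, k = k),
    class = "cross_basis"
  )
}

#' @export
print.cross_basis <- function(x, ...) {
  cat(sprintf("<cross_basis> K = %d (d_X = %d, d_Y = %d, n_train = %d)\n",
              x$k, nrow(x$u), nrow(x$v), x$n_train))
  invisible(x)
}

## Project test matrices into the basis's latent space. Raw rows are
## centered by the *training* means before rotation.
project_test <- function(basis, test_a, test_b, swap_projections = FALSE) {
  a <- as_values(test_a); b <- as_values(test_b)
  if (nrow(a) != nrow(b)) abort("test matrices must have equal row counts")
  if (nrow(a) < 2L) abort("need at least 2 test rows")
  if (ncol(a) != length(basis$mean_a) || ncol(b) != length(basis$mean_b)) {
    abort(sprintf("column-count mismatch: basis expects %d x %d channels, got %d x %d",
                  length(basis$mean_a), length(basis$mean_b), ncol(a), ncol(b)))
  }
  ra <- if (swap_projections) basis$v else basis$u
  rb <- if (swap_projections) basis$u else basis$v
  if (swap_projections && ncol(a) != nrow(ra)) {
    abort("swapped projections require d_X == d_Y")
  }
  list(a = center_cols(a, basis$mean_a) %*% ra,
       b = center_cols(b, basis$mean_b) %*% rb)
}

## Diagonal of the latent-space covariance (population, mean-subtracted).
latent_cov_diag <- function(pa, pb) {
  colMeans(pa * pb) - colMeans(pa) * colMeans(pb)
}

new_fold_spectrum <- function(rank, value, fold = NA_integer_, normalized = FALSE) {
  out <- tibble(fold = as.integer(fold), rank = as.integer(rank), value = value)
  structure(out, class = c("fold_spectrum", class(tibble())), normalized = normalized)
}

#' Evaluate the cross-validated spectrum on held-out stimuli
#'
#' Projects held-out test rows — centered by the basis's *training* means,
#' never the test means — onto the shared latent space and returns the
#' diagonal of the latent-space covariance (population `1/n` scaling, with
#' the projections' sample means subtracted). The entries are *signed*: a
#' latent dimension that does not generalize has expected test value zero,
#' which is the property the permutation null exploits.
#'
#' Reusing the training data as the test data reproduces `sigma_train`
#' exactly, because training projections have exactly zero mean.
#'
#' @param basis A [fit_cross_basis()] result.
#' @param test_a,test_b Held-out matrices (or [response_set()]s) with
#'   channel counts matching the basis and at least 2 rows.
#' @param fold Optional fold index recorded in the output.
#' @return A `fold_spectrum` tibble with columns `fold`, `rank`, `value`
#'   (length K), attribute `normalized = FALSE`.
#' @export
evaluate_test_spectrum <- function(basis, test_a, test_b, fold = NA_integer_) {
  p <- project_test(basis, test_a, test_b)
  new_fold_spectrum(seq_len(basis$k), latent_cov_diag(p$a, p$b), fold = fold)
}

#' Off-diagonal mass of the projected test covariance
#'
#' The cross-decomposition keeps only the diagonal of the latent-space test
#' covariance; this diagnostic reports the Frobenius norm of the
#' off-diagonal part relative to the Frobenius norm of the full matrix. For
#' matched train/test distributions the matrix is quasi-diagonal and the
#' ratio shrinks with the training-set size; for unrelated test data it is
#' near 1 (the diagonal carries no special mass).
#'
#' @inheritParams evaluate_test_spectrum
#' @return A single number in `[0, 1]`; 0 when the full norm is zero.
#' @export
offdiagonal_mass <- function(basis, test_a, test_b) {
  p <- project_test(basis, test_a, test_b)
  n <- nrow(p$a)
  m <- crossprod(center_cols(p$a), center_cols(p$b)) / n
  tot <- sqrt(sum(m^2))
  if (tot == 0) return(0)
  off <- m - diag(diag(m), nrow = nrow(m))
  sqrt(sum(off^2)) / tot
}

#' Normalize a spectrum by the geometric mean of the channel counts
#'
#' Divides every spectrum value by `sqrt(d_X * d_Y)` so that spectra from
#' regions of different sizes are comparable. For fully z-scored data the
#' total (training) variance equals the channel count, so the normalized
#' training spectrum of a self-decomposition cumulatively sums to 1.
#'
#' @param spec A `fold_spectrum` tibble (from [evaluate_test_spectrum()]).
#' @param d_x,d_y Channel counts of the two sides.
#' @return The spectrum with values divided by `sqrt(d_x * d_y)` and the
#'   `normalized` attribute set. Normalizing twice is an error.
#' @export
normalize_by_channels <- function(spec, d_x, d_y) {
  stopifnot(inherits(spec, "fold_spectrum"))
  if (isTRUE(attr(spec, "normalized"))) abort("spectrum is already channel-normalized")
  spec$value <- spec$value / sqrt(as.numeric(d_x) * as.numeric(d_y))
  attr(spec, "normalized") <- TRUE
  spec
}
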