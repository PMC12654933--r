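## Permutation-null calibration of cross-validated spectra.

## Per-fold latent projections for one trial pair. Projections are centered
## by training means (raw space); the latent covariance later subtracts the
## projections' own means. Ranks truncated to the common K across folds.
prepare_pair_projections <- function(a, b, folds, swap_projections = FALSE) {
  pv <- paired_values(a, b)
  f <- fold_of(folds, pv$ids)
  used <- sort(unique(f))
  d_x <- ncol(pv$a); d_y <- ncol(pv$b)
  n_train_min <- min(vapply(used, function(ff) sum(f != ff), integer(1)))
  k <- min(d_x, d_y, n_train_min - 1L)
  per_fold <- lapply(used, function(ff) {
    tr <- f != ff
    basis <- fit_cross_basis(pv$a[tr, , drop = FALSE], pv$b[tr, , drop = FALSE])
    p <- project_test(basis, pv$a[!tr, , drop = FALSE], pv$b[!tr, , drop = FALSE],
                      swap_projections = swap_projections)
    list(fold = ff, pa = p$a[, seq_len(k), drop = FALSE],
         pb = p$b[, seq_len(k), drop = FALSE])
  })
  list(per_fold = per_fold, k = k, norm = sqrt(d_x * d_y))
}

#' Spectrum under a stimulus-label permutation
#'
#' Identical to [evaluate_test_spectrum()] except that the given
#' permutation is applied to the rows of `test_b` first, destroying the
#' stimulus correspondence between the two sides. Under any permutation the
#' latent covariance has expectation zero per rank, which is the basis of
#' the permutation null.
#'
#' @inheritParams evaluate_test_spectrum
#' @param permutation Integer vector: a bijection of the test rows.
#' @return A `fold_spectrum` tibble.
#' @export
permuted_spectrum <- function(basis, test_a, test_b, permutation, fold = NA_integer_) {
  b <- as_values(test_b)
  n <- nrow(b)
  permutation <- as.integer(permutation)
  if (length(permutation) != n || !setequal(permutation, seq_len(n))) {
    abort("`permutation` must be a bijection on the test rows")
  }
  evaluate_test_spectrum(basis, test_a, b[permutation, , drop = FALSE], fold = fold)
}

#' Permutation-null ensemble of binned spectra
#'
#' Recomputes the configured cross-validated, binned, fold-averaged
#' spectrum `n_perms` times with the held-out rows of the second side
#' shuffled within each test fold (a fresh independent permutation per fold
#' and draw). The pipeline — folds, truncation, channel normalization,
#' binning, fold averaging — is exactly the one used for the observed
#' spectrum, so the ensemble is its calibrated null. Returns empirical
#' percentile envelopes at 68/95/99 per bin.
#'
#' @param x1,x2 Trial pair of the (first) system.
#' @param folds A [make_folds()] plan.
#' @param scheme A [make_log_bins()] scheme.
#' @param n_perms Number of permutations (default 5000; fewer than 100
#'   triggers a warning about percentile instability).
#' @param seed Integer seed; the ensemble is deterministic given the seed.
#' @param y1,y2 Second system's trials for `mode = "between"` or
#'   `"anatomical"`.
#' @param mode Estimator to calibrate: `"within"` (default), `"between"`,
#'   or `"anatomical"`.
#' @return An object of class `null_ensemble`: list with `bins` (tibble of
#'   `bin`, `bin_center`, `n_ranks`, `mean`, `p68`, `p95`, `p99`), the
#'   `draws` matrix (`n_perms` × bins), `n_perms` and `seed`.
#' @export
build_null_ensemble <- function(x1, x2, folds, scheme, n_perms = 5000L,
                                seed = 1L, y1 = NULL, y2 = NULL,
                                mode = c("within", "between", "anatomical")) {
  mode <- match.arg(mode)
  n_perms <- as.integer(n_perms)
  if (n_perms < 1L) abort("`n_perms` must be positive")
  if (n_perms < 100L) warn("fewer than 100 permutations: percentile envelopes will be unstable")
  preps <- switch(mode,
    within = list(prepare_pair_projections(x1, x2, folds)),
    between = {
      if (is.null(y1) || is.null(y2)) abort("between mode needs y1 and y2")
      list(prepare_pair_projections(x1, y2, folds),
           prepare_pair_projections(x2, y1, folds))
    },
    anatomical = {
      if (is.null(y1) || is.null(y2)) abort("anatomical mode needs y1 and y2")
      check_common_channels(x1, y1)
      list(prepare_pair_projections(x1, y2, folds, swap_projections = TRUE),
           prepare_pair_projections(x2, y1, folds, swap_projections = TRUE))
    })
  k <- min(vapply(preps, function(p) p$k, integer(1)))
  binf <- bin_membership(scheme, seq_len(k))
  if (anyNA(binf)) abort("bin scheme does not cover all ranks of the estimator")
  bins <- sort(unique(binf))
  counts <- as.vector(table(factor(binf, levels = bins)))
  centers <- vapply(bins, function(b) geomean(which(binf == b)), numeric(1))

  ## pre-center projections once; a row permutation leaves means unchanged
  for (i in seq_along(preps)) {
    preps[[i]]$per_fold <- lapply(preps[[i]]$per_fold, function(pf) {
      pf$pa <- center_cols(pf$pa[, seq_len(k), drop = FALSE])
      pf$pb <- center_cols(pf$pb[, seq_len(k), drop = FALSE])
      pf
    })
  }
  n_folds_used <- length(preps[[1]]$per_fold)
  draws <- matrix(NA_real_, n_perms, length(bins))
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perms)) {
      acc <- numeric(length(bins))
      for (fi in seq_len(n_folds_used)) {
        val <- numeric(k)
        for (pr in preps) {
          pf <- pr$per_fold[[fi]]
          nt <- nrow(pf$pa)
          perm <- sample.int(nt)
          val <- val + colSums(pf$pa * pf$pb[perm, , drop = FALSE]) / nt / pr$norm
        }
        val <- val / length(preps)
        acc <- acc + rowsum(val, binf)[, 1] / counts
      }
      draws[p, ] <- acc / n_folds_used
    }
  })
  qs <- apply(draws, 2, stats::quantile, probs = c(0.68, 0.95, 0.99), names = FALSE)
  structure(
    list(bins = tibble(bin = bins, bin_center = centers, n_ranks = counts,
                       mean = colMeans(draws),
                       p68 = qs[1, ], p95 = qs[2, ], p99 = qs[3, ]),
         draws = draws, n_perms = n_perms, seed = as.integer(seed), mode = mode),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s mode, %d permutations, %d bins\n",
              x$mode, x$n_perms, nrow(x$bins)))
  invisible(x)
}

#' Flag per-bin significance against a permutation null
#'
#' One-sided, add-one permutation p-value per bin:
#' `p = (1 + #\{null >= observed\}) / (n_perms + 1)` — never exactly zero —
#' with `significant = p < alpha`. The default `alpha = 0.001` matches the
#' usual open-symbol convention and requires at least 999 permutations.
#'
#' @param observed A `binned_spectrum` from [aggregate_folds()].
#' @param null A [build_null_ensemble()] result on the same bin scheme.
#' @param alpha Significance level (default 0.001).
#' @return The `binned_spectrum` with `p_value` and `significant` columns
#'   added.
#' @export
flag_significance <- function(observed, null, alpha = 0.001) {
  stopifnot(inherits(null, "null_ensemble"))
  if (alpha < 1 / (null$n_perms + 1)) {
    abort(sprintf("alpha = %g is unattainable with %d permutations (minimum p is %g)",
                  alpha, null$n_perms, 1 / (null$n_perms + 1)))
  }
  idx <- match(observed$bin, null$bins$bin)
  if (anyNA(idx)) abort("observed and null use different bin schemes")
  exceed <- vapply(seq_along(idx), function(i) {
    sum(null$draws[, idx[i]] >= observed$mean[i])
  }, numeric(1))
  observed$p_value <- (1 + exceed) / (null$n_perms + 1)
  observed$significant <- observed$p_value < alpha
  observed
}

#' Export null percentile envelopes to CSV
#'
#' @param null A [build_null_ensemble()] result.
#' @param path Output CSV path.
#' @export
write_null_csv <- function(null, path) {
  stopifnot(inherits(null, "null_ensemble"))
  readr::write_csv(null$bins, path, progress = FALSE)
  invisible(path)
}
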