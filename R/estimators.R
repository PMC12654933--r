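## Fold-looped spectral estimators built on fit_cross_basis /
## evaluate_test_spectrum.

## Check two response sets cover the identical stimulus set and return
## their value matrices with rows in canonical (lexicographic) order.
paired_values <- function(a, b, what = "response sets") {
  ia <- stim_ids(a); ib <- stim_ids(b)
  if (is.null(ia) || is.null(ib) || !setequal(ia, ib) || length(ia) != length(ib)) {
    abort(sprintf("%s must be paired on an identical stimulus set", what))
  }
  ord <- sort_c(ia)
  list(a = as_values(a)[match(ord, ia), , drop = FALSE],
       b = as_values(b)[match(ord, ib), , drop = FALSE],
       ids = ord)
}

## Fold membership (named by stimulus id) for a stimulus order.
fold_of <- function(folds, ids) {
  stopifnot(inherits(folds, "fold_plan"))
  f <- folds$fold[match(ids, folds$stimulus_id)]
  if (anyNA(f)) abort("fold plan does not cover all paired stimuli")
  f
}

## One pair of trials, all folds: fit on 7/8, evaluate on the held-out 1/8.
## Ranks are truncated to the smallest K across folds so fold spectra align.
crossdecomp_pair <- function(a, b, folds, swap_projections = FALSE,
                             normalize = TRUE) {
  pv <- paired_values(a, b)
  f <- fold_of(folds, pv$ids)
  used <- sort(unique(f))
  d_x <- ncol(pv$a); d_y <- ncol(pv$b)
  n_train_min <- min(vapply(used, function(ff) sum(f != ff), integer(1)))
  k_common <- min(d_x, d_y, n_train_min - 1L)
  specs <- lapply(used, function(ff) {
    tr <- f != ff
    basis <- fit_cross_basis(pv$a[tr, , drop = FALSE], pv$b[tr, , drop = FALSE])
    p <- project_test(basis, pv$a[!tr, , drop = FALSE], pv$b[!tr, , drop = FALSE],
                      swap_projections = swap_projections)
    s <- new_fold_spectrum(seq_len(basis$k), latent_cov_diag(p$a, p$b), fold = ff)
    s[s$rank <= k_common, , drop = FALSE]
  })
  out <- dplyr::bind_rows(specs)
  out <- structure(out, class = c("fold_spectrum", class(tibble())),
                   normalized = FALSE)
  if (normalize) out <- normalize_by_channels(out, d_x, d_y)
  out
}

#' Within-system cross-validated spectrum
#'
#' The cross-decomposition of two trials (repeated presentations of the
#' same stimuli) of one system: per fold, the aligned basis is learned on
#' the other folds' stimuli and the signed spectrum is evaluated on the
#' held-out fold, then channel-normalized. The result estimates the
#' spectrum of stimulus-related variance that is reliable across trials
#' *and* generalizes to new stimuli.
#'
#' @param trial1,trial2 [response_set()]s paired on the identical stimulus
#'   set (order may differ).
#' @param folds A [make_folds()] plan covering those stimuli.
#' @return A normalized `fold_spectrum` tibble with columns `fold`, `rank`,
#'   `value` (one spectrum per fold).
#' @seealso [between_system_spectrum()], [bin_spectrum()]
#' @export
within_system_spectrum <- function(trial1, trial2, folds) {
  crossdecomp_pair(trial1, trial2, folds)
}

#' Between-system symmetrized cross-validated spectrum
#'
#' Cross-decomposition between two systems (subjects or regions) with two
#' trials each. Because trial order is arbitrary, the estimate is the
#' average of the two cross-trial spectra, `(S(x1, y2) + S(x2, y1)) / 2`,
#' per fold and rank, which makes it insensitive to swapping trial labels
#' within either system.
#'
#' @param x1,x2 Two trials of system X.
#' @param y1,y2 Two trials of system Y.
#' @inheritParams within_system_spectrum
#' @return A normalized `fold_spectrum` tibble.
#' @export
between_system_spectrum <- function(x1, x2, y1, y2, folds) {
  average_pair_spectra(
    crossdecomp_pair(x1, y2, folds),
    crossdecomp_pair(x2, y1, folds)
  )
}

average_pair_spectra <- function(s1, s2) {
  stopifnot(identical(dim(s1), dim(s2)))
  merged <- dplyr::inner_join(s1, s2, by = c("fold", "rank"),
                              suffix = c("_1", "_2"))
  out <- tibble(fold = merged$fold, rank = merged$rank,
                value = (merged$value_1 + merged$value_2) / 2)
  structure(out, class = c("fold_spectrum", class(tibble())),
            normalized = attr(s1, "normalized"))
}

#' Anatomically aligned between-system spectrum
#'
#' Identical to [between_system_spectrum()] except that the projection
#' matrices are exchanged at test time: test data from X are projected onto
#' `V` and test data from Y onto `U`. This assumes channel-for-channel
#' correspondence between the systems (same channels, identically ordered),
#' i.e. that no subject-specific rotation is needed. Where that assumption
#' fails — which is the empirical norm beyond the leading dimensions — the
#' anatomical spectrum collapses to the permutation null while the
#' functional estimator keeps detecting shared variance.
#'
#' @inheritParams between_system_spectrum
#' @return A normalized `fold_spectrum` tibble.
#' @export
anatomical_spectrum <- function(x1, x2, y1, y2, folds) {
  check_common_channels(x1, y1)
  average_pair_spectra(
    crossdecomp_pair(x1, y2, folds, swap_projections = TRUE),
    crossdecomp_pair(x2, y1, folds, swap_projections = TRUE)
  )
}

check_common_channels <- function(a, b) {
  if (!inherits(a, "response_set") || !inherits(b, "response_set")) {
    if (ncol(as_values(a)) != ncol(as_values(b))) {
      abort("anatomical mode requires a common channel space (equal, identically ordered channels)")
    }
    return(invisible(TRUE))
  }
  if (!identical(a$channel_ids, b$channel_ids)) {
    abort("anatomical mode requires a common channel space (equal, identically ordered channels)")
  }
  invisible(TRUE)
}

#' PCA eigenvalue spectrum
#'
#' Eigenvalues of the self-covariance `(1/n) t(X_c) X_c` — all variance,
#' stimulus-related signal and noise alike, which is why PCA overestimates
#' reliable dimensionality. Retains `K = min(d, n - 1)` components.
#'
#' @param x A [response_set()] or numeric matrix.
#' @return A tibble with columns `rank` and `value` (nonincreasing).
#' @export
pca_spectrum <- function(x) {
  v <- as_values(x)
  n <- nrow(v)
  cv <- crossprod(center_cols(v)) / n
  k <- min(ncol(v), n - 1L)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values[seq_len(k)]
  tibble(rank = seq_len(k), value = ev)
}

#' Cross-validated PCA (cvPCA) spectrum
#'
#' Principal axes are learned from the trial-1 covariance over the full
#' stimulus set; the spectrum is the diagonal of the covariance between the
#' two trials' projections on those axes. This measures reliability across
#' stimulus repeats but — deliberately, and unlike the cross-decomposition —
#' involves no held-out stimulus split, so it does not test generalization
#' to new stimuli. Provided as a comparison estimator.
#'
#' @param x1,x2 Two trials of one system, paired on identical stimuli.
#' @return A `fold_spectrum` tibble (single fold) with columns `fold`,
#'   `rank`, `value`.
#' @export
cvpca_spectrum <- function(x1, x2) {
  pv <- paired_values(x1, x2, "cvPCA trials")
  n <- nrow(pv$a)
  k <- min(ncol(pv$a), n - 1L)
  w <- eigen(crossprod(center_cols(pv$a)) / n, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  pa <- center_cols(pv$a) %*% w
  pb <- center_cols(pv$b) %*% w
  new_fold_spectrum(seq_len(k), latent_cov_diag(pa, pb), fold = 1L)
}
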