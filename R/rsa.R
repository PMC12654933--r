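#' Representational similarity matrix
#'
#' Entry (i, j) is the Pearson correlation between the channel patterns of
#' stimuli i and j (rows of the response matrix).
#'
#' @param rs A [response_set()] with `d >= 2` channels; every stimulus
#'   pattern must have nonzero spread.
#' @return An `n` × `n` matrix of class `rsm` (symmetric, unit diagonal),
#'   dimnames = stimulus ids.
#' @export
compute_rsm <- function(rs) {
  v <- as_values(rs)
  if (ncol(v) < 2L) abort("RSMs need at least 2 channels")
  spread <- apply(v, 1L, stats::sd)
  bad <- which(spread <= 0 | !is.finite(spread))
  if (length(bad)) {
    ids <- stim_ids(rs)
    lab <- if (is.null(ids)) as.character(bad) else ids[bad]
    abort(sprintf("zero-spread pattern for stimuli: %s", paste(lab, collapse = ", ")))
  }
  r <- stats::cor(t(v))
  structure(r, class = c("rsm", class(r)), method = "pearson")
}

#' Reconstruct responses from leading principal components
#'
#' Centers the data, projects onto the first `n_components` principal
#' axes, reconstructs, and adds the mean back. Used as the "low-D" control:
#' variance-weighted similarity metrics barely notice this truncation even
#' though everything beyond rank `n_components` is removed.
#'
#' @param rs A [response_set()].
#' @param n_components Number of components, `1 <= n_components <=
#'   min(n - 1, d)`.
#' @return A [response_set()] of reconstructed values.
#' @export
low_rank_reconstruct <- function(rs, n_components) {
  v <- as_values(rs)
  n_components <- as.integer(n_components)
  kmax <- min(nrow(v) - 1L, ncol(v))
  if (n_components < 1L || n_components > kmax) {
    abort(sprintf("`n_components` must be in 1..%d", kmax))
  }
  mu <- colMeans(v)
  sv <- svd(center_cols(v, mu), nu = n_components, nv = n_components)
  rec <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
  rec <- sweep(rec, 2L, mu, `+`)
  if (inherits(rs, "response_set")) {
    response_set(rec, stimulus_ids = rs$stimulus_ids, channel_ids = rs$channel_ids,
                 subject_id = rs$subject_id, region_id = rs$region_id,
                 trial_index = rs$trial_index)
  } else rec
}

#' Correlation between two representational similarity matrices
#'
#' Correlates the strictly-upper-triangle entries (the diagonal is
#' uninformative and would inflate agreement) using Pearson or Spearman
#' correlation.
#'
#' @param a,b `rsm` matrices over the same ordered stimulus set.
#' @param method `"pearson"` or `"spearman"`.
#' @return A single correlation coefficient.
#' @export
rsa_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(dim(a), dim(b))) abort("RSMs must have identical dimensions")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("RSMs must cover the same ordered stimulus set")
  }
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort("constant upper triangle: RSA correlation undefined")
  }
  stats::cor(va, vb, method = method)
}

#' Bootstrap distribution of an RSA correlation
#'
#' Per resample, a fraction of the stimuli is subsampled *without*
#' repetition, both RSMs are recomputed on the subsample, and their
#' correlation is recorded. Summaries use 2-standard-deviation error bars
#' over the bootstrap distribution.
#'
#' @param a_data,b_data [response_set()]s over the same ordered stimuli.
#' @param n_boot Number of resamples (default 5000).
#' @param fraction Subsample fraction in (0, 1] (default 0.9).
#' @param seed Integer seed.
#' @param method Correlation method, as [rsa_correlation()].
#' @return A tibble of class `rsa_bootstrap` with columns `draw`, `r`;
#'   attributes `point_estimate` (full-data correlation), `mean`, `sd`,
#'   `method`, `fraction`, `seed`.
#' @export
bootstrap_rsa <- function(a_data, b_data, n_boot = 5000L, fraction = 0.9,
                          seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pv <- paired_values(a_data, b_data, "RSA inputs")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  n <- nrow(pv$a)
  m <- floor(fraction * n)
  if (m < 3L) abort("subsample would have fewer than 3 stimuli")
  point <- rsa_correlation(compute_rsm(pv$a), compute_rsm(pv$b), method)
  rs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(as.integer(n_boot)), function(i) {
      idx <- if (m == n) seq_len(n) else sample.int(n, m)
      rsa_correlation(compute_rsm(pv$a[idx, , drop = FALSE]),
                      compute_rsm(pv$b[idx, , drop = FALSE]), method)
    }, numeric(1))
  })
  structure(tibble(draw = seq_along(rs), r = rs),
            class = c("rsa_bootstrap", class(tibble())),
            point_estimate = point, mean = mean(rs), sd = stats::sd(rs),
            method = method, fraction = fraction, seed = as.integer(seed))
}
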