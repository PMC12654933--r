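#' Logarithmic rank-binning scheme
#'
#' Builds geometrically spaced bin edges spanning `[k_min, k_max]`. An
#' integer rank `k` belongs to bin `j` iff `edge_j <= k < edge_{j+1}`, with
#' the last bin right-inclusive. Bins containing no integer rank are
#' dropped with a warning. The default density of 2.75 bins per decade over
#' ranks 1 to 10^4 yields 11 bins — wide enough at high rank to average
#' away noise, narrow enough to resolve the spectral shape.
#'
#' @param k_min,k_max Integer rank range (`1 <= k_min < k_max`).
#' @param per_decade Approximate bin density per decade of rank
#'   (default 2.75).
#' @return A `bin_scheme`: a tibble with columns `bin`, `lower`, `upper`
#'   and attribute `edges`.
#' @examples
#' scheme <- make_log_bins(1, 10000)
#' nrow(scheme)  # 11 bins
#' @export
make_log_bins <- function(k_min = 1L, k_max = 10000L, per_decade = 2.75) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_min >= k_max) abort("need 1 <= k_min < k_max")
  if (per_decade <= 0) abort("`per_decade` must be positive")
  n_bins <- max(1L, as.integer(round(per_decade * log10(k_max / k_min))))
  edges <- exp(seq(log(k_min), log(k_max), length.out = n_bins + 1L))
  edges[1] <- k_min                 # snap endpoints: integer ranks at the
  edges[length(edges)] <- k_max     # boundaries must fall inside the scheme
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  ranks <- seq.int(k_min, k_max)
  memb <- bin_index_raw(ranks, edges)
  keep <- sort(unique(memb))
  if (length(keep) < n_bins) {
    warn(sprintf("dropping %d empty bin(s) with no integer ranks", n_bins - length(keep)))
  }
  out <- tibble(bin = seq_along(keep), lower = lower[keep], upper = upper[keep])
  structure(out, class = c("bin_scheme", class(tibble())),
            edges = edges, kept = keep, k_min = k_min, k_max = k_max)
}

## raw bin index against full edge list (before empty-bin dropping);
## last bin right-inclusive
bin_index_raw <- function(ranks, edges) {
  b <- findInterval(ranks, edges, rightmost.closed = TRUE)
  b[ranks < edges[1] | ranks > edges[length(edges)]] <- NA_integer_
  b
}

#' @rdname make_log_bins
#' @param scheme A `bin_scheme`.
#' @param ranks Integer ranks to classify.
#' @return `bin_membership()` returns the bin index of each rank (`NA`
#'   outside the scheme's range).
#' @export
bin_membership <- function(scheme, ranks) {
  stopifnot(inherits(scheme, "bin_scheme"))
  raw <- bin_index_raw(ranks, attr(scheme, "edges"))
  match(raw, attr(scheme, "kept"))
}

#' Average a spectrum within logarithmic rank bins
#'
#' Per fold and bin: the arithmetic mean of the member ranks' values, the
#' geometric mean of the member ranks (bin center), and the member count.
#' Bins beyond the spectrum's maximum rank are dropped; every rank of the
#' spectrum must be covered by the scheme.
#'
#' @param spec A `fold_spectrum` tibble (columns `fold`, `rank`, `value`).
#' @param scheme A [make_log_bins()] scheme covering ranks `1..K`.
#' @return A tibble of class `binned_folds` with columns `fold`, `bin`,
#'   `bin_center`, `value`, `n_ranks`; the `normalized` attribute is
#'   carried through.
#' @export
bin_spectrum <- function(spec, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (!all(c("rank", "value") %in% names(spec))) {
    abort("`spec` must have columns `rank` and `value`")
  }
  if (!("fold" %in% names(spec))) spec$fold <- NA_integer_
  b <- bin_membership(scheme, spec$rank)
  if (anyNA(b)) abort("bin scheme does not cover all ranks of the spectrum")
  out <- tibble(fold = spec$fold, bin = b, rank = spec$rank, value = spec$value) |>
    dplyr::group_by(.data$fold, .data$bin) |>
    dplyr::summarise(bin_center = geomean(.data$rank),
                     value = mean(.data$value),
                     n_ranks = dplyr::n(), .groups = "drop")
  structure(out, class = c("binned_folds", class(tibble())),
            normalized = attr(spec, "normalized"))
}

#' Aggregate binned spectra across cross-validation folds
#'
#' Per bin: the mean and the population (divide-by-m) standard deviation of
#' the fold values. With a single fold the dispersion is reported as `NA`.
#'
#' @param binned A `binned_folds` tibble from [bin_spectrum()].
#' @return A tibble of class `binned_spectrum` with columns `bin`,
#'   `bin_center`, `mean`, `sd`, `n_ranks`, `n_folds`.
#' @export
aggregate_folds <- function(binned) {
  if (!all(c("bin", "bin_center", "value") %in% names(binned))) {
    abort("`binned` must come from bin_spectrum()")
  }
  out <- binned |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(bin_center = .data$bin_center[1],
                     mean = mean(.data$value),
                     sd = sd_pop(.data$value),
                     n_ranks = .data$n_ranks[1],
                     n_folds = dplyr::n(), .groups = "drop")
  structure(out, class = c("binned_spectrum", class(tibble())),
            normalized = attr(binned, "normalized"))
}

#' Export a binned spectrum (or correlation table) to CSV
#'
#' Writes the columns as-is, suitable for log-log plotting elsewhere.
#'
#' @param x A `binned_spectrum` or `spectral_correlation` tibble.
#' @param path Output CSV path.
#' @export
write_spectrum_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
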