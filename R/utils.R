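## Internal helpers shared across modules.

## Population (divide-by-n) column standard deviation.
col_sd_pop <- function(x) {
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

## Population sd of a vector; NA for a single value.
sd_pop <- function(x) {
  m <- length(x)
  if (m < 2) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / m)
}

## Sweep column means out of a matrix (optionally externally supplied).
center_cols <- function(x, mu = NULL) {
  if (is.null(mu)) mu <- colMeans(x)
  sweep(x, 2L, mu, `-`)
}

## Geometric mean.
geomean <- function(x) exp(mean(log(x)))

## Coerce a response_set or matrix to a plain numeric matrix.
as_values <- function(x) {
  if (inherits(x, "response_set")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  abort("expected a response_set or a numeric matrix")
}

## Stimulus ids of a response_set (or rownames of a matrix).
stim_ids <- function(x) {
  if (inherits(x, "response_set")) return(x$stimulus_ids)
  rownames(x)
}

## Locale-independent lexicographic sort (C collation).
sort_c <- function(x) sort(x, method = "radix")
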