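#' Between-system spectral correlation coefficient
#'
#' Per (wide) rank bin, the ratio of the between-system cross-validated
#' spectrum to the geometric mean of the two within-system spectra:
#' `r = between / sqrt(within_a * within_b)`. Like a Pearson correlation it
#' is invariant to a common rescaling of either system, but every term is
#' evaluated on held-out stimuli, so chance alignment does not inflate it.
#' Because the ratio amplifies noise, wider bins than those used for the
#' spectra themselves are recommended (about 2 per decade).
#'
#' All three inputs must be per-fold binned spectra ([bin_spectrum()]
#' output) on the *same* bin scheme. The point estimate per bin is the
#' ratio of fold-averaged means; the dispersion is the population standard
#' deviation across per-fold ratios (folds where either denominator is
#' non-positive are skipped). A bin is `valid` only where both fold-mean
#' denominators are strictly positive, and is `flagged` where the
#' between-system mean lies less than three across-fold standard deviations
#' above zero (the open-symbol convention).
#'
#' @param between `binned_folds` for the between-system spectrum.
#' @param within_a,within_b `binned_folds` for the two within-system
#'   spectra.
#' @return A tibble of class `spectral_correlation` with columns `bin`,
#'   `bin_center`, `r`, `sd`, `valid`, `flagged`.
#' @export
spectral_correlation <- function(between, within_a, within_b) {
  for (x in list(between, within_a, within_b)) {
    if (!all(c("fold", "bin", "bin_center", "value") %in% names(x))) {
      abort("all inputs must be per-fold binned spectra from bin_spectrum()")
    }
  }
  bt <- aggregate_folds(between)
  wa <- aggregate_folds(within_a)
  wb <- aggregate_folds(within_b)
  if (!identical(bt$bin, wa$bin) || !identical(bt$bin, wb$bin) ||
      max(abs(bt$bin_center - wa$bin_center), abs(bt$bin_center - wb$bin_center)) > 1e-8) {
    abort("between and within spectra must use the same bin scheme")
  }
  valid <- wa$mean > 0 & wb$mean > 0
  r <- ifelse(valid, bt$mean / sqrt(wa$mean * wb$mean), NA_real_)

  per_fold <- dplyr::inner_join(
    dplyr::inner_join(as_tibble(between)[, c("fold", "bin", "value")],
                      as_tibble(within_a)[, c("fold", "bin", "value")],
                      by = c("fold", "bin"), suffix = c("_b", "_wa")),
    as_tibble(within_b)[, c("fold", "bin", "value")], by = c("fold", "bin"))
  names(per_fold)[names(per_fold) == "value"] <- "value_wb"
  fold_sd <- per_fold |>
    dplyr::filter(.data$value_wa > 0, .data$value_wb > 0) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(sd = sd_pop(.data$value_b / sqrt(.data$value_wa * .data$value_wb)),
                     .groups = "drop")
  out <- tibble(bin = bt$bin, bin_center = bt$bin_center, r = r,
                sd = fold_sd$sd[match(bt$bin, fold_sd$bin)],
                valid = valid,
                flagged = !is.finite(bt$sd) | bt$mean < 3 * bt$sd)
  structure(out, class = c("spectral_correlation", class(tibble())))
}
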