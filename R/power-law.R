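#' Fit a power law to a binned spectrum
#'
#' Unweighted ordinary least squares of `log10(mean)` on `log10(bin_center)`
#' over the bins whose mean is strictly positive and whose center falls in
#' `fit_range`. The slope is the power-law exponent (e.g. about -1.6 for
#' cross-validated cortical spectra); negative bin means — legitimate for a
#' signed estimator — are excluded from the fit.
#'
#' @param bs A `binned_spectrum` tibble from [aggregate_folds()] (any tibble
#'   with `bin_center` and `mean` columns works).
#' @param fit_range Length-2 numeric rank interval; bins with centers inside
#'   (inclusive) are used. Default covers everything.
#' @return An object of class `power_law_fit` with fields `exponent`,
#'   `amplitude`, `fit_range`, `n_points` and the underlying `lm` model.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' bs <- tibble::tibble(bin_center = 10^seq(0, 3, length.out = 8),
#'                      mean = 2 * (10^seq(0, 3, length.out = 8))^-1.6)
#' fit_power_law(bs)$exponent
#' @export
fit_power_law <- function(bs, fit_range = c(1, Inf)) {
  stopifnot(length(fit_range) == 2L, fit_range[1] < fit_range[2])
  use <- bs$mean > 0 & bs$bin_center >= fit_range[1] & bs$bin_center <= fit_range[2]
  if (sum(use) < 3L) {
    abort(sprintf("need at least 3 positive bins inside fit_range, have %d", sum(use)))
  }
  dat <- data.frame(lx = log10(bs$bin_center[use]), ly = log10(bs$mean[use]))
  model <- stats::lm(ly ~ lx, data = dat)
  co <- stats::coef(model)
  structure(
    list(exponent = unname(co["lx"]), amplitude = 10^unname(co["(Intercept)"]),
         fit_range = fit_range, n_points = sum(use), model = model),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent %.3f (amplitude %.3g, %d bins in [%g, %g])\n",
              x$exponent, x$amplitude, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @export
tidy.power_law_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("amplitude_log10", "exponent"),
         estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p.value = unname(s[, "Pr(>|t|)"]))
}

#' @rdname fit_power_law
#' @export
glance.power_law_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(exponent = x$exponent, amplitude = x$amplitude,
         r.squared = s$r.squared, sigma = s$sigma,
         n_points = x$n_points,
         fit_min = x$fit_range[1], fit_max = x$fit_range[2])
}
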