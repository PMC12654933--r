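#' Sample a Gabor filter on the image raster
#'
#' The filter is a Gaussian envelope times a sinusoidal carrier,
#' `g = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi f x' + psi)`,
#' with `x' = x cos(theta) + y sin(theta)` and
#' `y' = -x sin(theta) + y cos(theta)` measured from the filter center.
#' Coordinates are relative image units: the square image has side 1 and
#' its center is at (0, 0). The kernel is sampled over the full raster (no
#' truncation window; the envelope decays to numerical zero).
#'
#' @param x,y Filter center in relative image units.
#' @param sigma Envelope scale (> 0).
#' @param gamma Aspect ratio of the envelope (> 0).
#' @param f Carrier spatial frequency (cycles per image side).
#' @param theta Orientation in `[0, pi)`.
#' @param psi Carrier phase; 0 gives the "odd" and `pi/2` the "even" member
#'   of a quadrature pair.
#' @param resolution Raster side in pixels (>= 8).
#' @return A `resolution` × `resolution` matrix (rows index y, columns x).
#' @export
gabor_kernel <- function(x = 0, y = 0, sigma = 0.05, gamma = 1, f = 2,
                         theta = 0, psi = 0, resolution = 128L) {
  resolution <- as.integer(resolution)
  if (resolution < 8L) abort("`resolution` must be at least 8")
  if (sigma <= 0 || gamma <= 0 || f <= 0) abort("sigma, gamma and f must be positive")
  g <- seq(-0.5 + 0.5 / resolution, 0.5 - 0.5 / resolution, length.out = resolution)
  xm <- matrix(g, resolution, resolution, byrow = TRUE) - x
  ym <- matrix(g, resolution, resolution) - y
  xp <- xm * cos(theta) + ym * sin(theta)
  yp <- -xm * sin(theta) + ym * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * f * xp + psi)
}

#' Gabor filter-bank configuration
#'
#' The default bank follows the standard energy-model construction:
#' 3 envelope scales, 3 carrier frequencies per scale, 8 orientations
#' uniform on `[0, pi)` and an 8 × 8 grid of centers in `[-0.45, 0.45]`,
#' giving 3 × 3 × 8 × 64 = 4,608 quadrature pairs and 13,824 features
#' (odd, even and energy per pair).
#'
#' The frequency rule is exposed as a convention flag because the printed
#' rule `f = 0.25 sigma, ...` multiplies a frequency by a length:
#' `"multiply"` (default) takes it literally, `f = mult * sigma`;
#' `"divide"` uses the dimensionally conventional `f = mult / sigma`, which
#' puts a fixed number of carrier cycles under the envelope.
#'
#' @param scales Envelope scales `sigma` (relative image units).
#' @param freq_mult Frequency multipliers applied per scale.
#' @param n_orientations Number of orientations, uniform on `[0, pi)`.
#' @param grid_n Centers per axis.
#' @param grid_range Range of center coordinates per axis.
#' @param gamma Aspect ratio (default 1).
#' @param frequency_convention `"multiply"` or `"divide"` (see above).
#' @param resolution Default raster side in pixels for feature extraction.
#' @return A list of class `gabor_bank_config`.
#' @export
gabor_bank_config <- function(scales = c(0.025, 0.050, 0.075),
                              freq_mult = c(0.25, 0.5, 0.75),
                              n_orientations = 8L, grid_n = 8L,
                              grid_range = c(-0.45, 0.45), gamma = 1,
                              frequency_convention = c("multiply", "divide"),
                              resolution = 128L) {
  structure(
    list(scales = scales, freq_mult = freq_mult,
         n_orientations = as.integer(n_orientations), grid_n = as.integer(grid_n),
         grid_range = grid_range, gamma = gamma,
         frequency_convention = match.arg(frequency_convention),
         resolution = as.integer(resolution)),
    class = "gabor_bank_config"
  )
}

#' Enumerate a Gabor bank's quadrature pairs
#'
#' @param cfg A [gabor_bank_config()].
#' @return A tibble of class `gabor_bank` with one row per quadrature pair
#'   (columns `pair`, `x`, `y`, `sigma`, `gamma`, `f`, `theta`) and
#'   attributes `config` and `n_features` (= 3 × pairs).
#' @examples
#' bank <- build_gabor_bank(gabor_bank_config())
#' nrow(bank)                  # 4608 quadrature pairs
#' attr(bank, "n_features")    # 13824 features
#' @export
build_gabor_bank <- function(cfg = gabor_bank_config()) {
  stopifnot(inherits(cfg, "gabor_bank_config"))
  centers <- seq(cfg$grid_range[1], cfg$grid_range[2], length.out = cfg$grid_n)
  theta <- seq(0, pi, length.out = cfg$n_orientations + 1L)[seq_len(cfg$n_orientations)]
  grid <- expand.grid(x = centers, y = centers, theta = theta,
                      mult = cfg$freq_mult, sigma = cfg$scales,
                      KEEP.OUT.ATTRS = FALSE)
  f <- if (cfg$frequency_convention == "multiply") {
    grid$mult * grid$sigma
  } else {
    grid$mult / grid$sigma
  }
  out <- tibble(pair = seq_len(nrow(grid)), x = grid$x, y = grid$y,
                sigma = grid$sigma, gamma = cfg$gamma, f = f, theta = grid$theta)
  structure(out, class = c("gabor_bank", class(tibble())),
            config = cfg, n_features = 3L * nrow(out))
}

#' Extract Gabor simple- and energy-model features from images
#'
#' For each quadrature pair, the odd (`psi = 0`) and even (`psi = pi/2`)
#' responses are the inner products of the image with the two kernels, and
#' the energy (complex-cell) feature is `odd^2 + even^2`. The three blocks
#' are concatenated and each feature is z-scored (population sd) across the
#' provided stimulus set. Filters are not norm-normalized — the z-scoring
#' absorbs scale.
#'
#' @param images A `count` × `res` × `res` array (e.g. from
#'   [generate_test_images()]) or a list of square matrices.
#' @param bank A [build_gabor_bank()] result.
#' @param resolution Raster side; defaults to the bank config's.
#' @param chunk_size Pairs rasterized per block (memory control).
#' @return An `n` × `3 * pairs` matrix of class `gabor_features` with
#'   attribute `metadata`: a tibble with `feature`, `kind`
#'   (odd/even/energy) and the pair parameters.
#' @export
extract_gabor_features <- function(images, bank, resolution = NULL,
                                   chunk_size = 256L) {
  stopifnot(inherits(bank, "gabor_bank"))
  cfg <- attr(bank, "config")
  if (is.null(resolution)) resolution <- cfg$resolution
  if (is.list(images)) {
    images <- simplify2array(images)        # res x res x n
    images <- aperm(images, c(3, 1, 2))
  }
  if (length(dim(images)) != 3L) abort("`images` must be a stack: count x res x res")
  n <- dim(images)[1]
  if (dim(images)[2] != dim(images)[3]) abort("images must be square")
  if (dim(images)[2] != resolution) abort("image resolution does not match the bank raster")
  imat <- matrix(images, nrow = n)          # n x res^2, column-major over (row, col)
  np <- nrow(bank)
  odd <- matrix(NA_real_, n, np); even <- matrix(NA_real_, n, np)
  for (start in seq(1L, np, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, np)
    ko <- vapply(idx, function(i) {
      as.vector(gabor_kernel(bank$x[i], bank$y[i], bank$sigma[i], bank$gamma[i],
                             bank$f[i], bank$theta[i], 0, resolution))
    }, numeric(resolution^2))
    ke <- vapply(idx, function(i) {
      as.vector(gabor_kernel(bank$x[i], bank$y[i], bank$sigma[i], bank$gamma[i],
                             bank$f[i], bank$theta[i], pi / 2, resolution))
    }, numeric(resolution^2))
    odd[, idx] <- imat %*% ko
    even[, idx] <- imat %*% ke
  }
  feats <- cbind(odd, even, odd^2 + even^2)
  meta <- tibble(
    feature = seq_len(3L * np),
    kind = rep(c("odd", "even", "energy"), each = np),
    pair = rep(bank$pair, 3L),
    x = rep(bank$x, 3L), y = rep(bank$y, 3L), sigma = rep(bank$sigma, 3L),
    f = rep(bank$f, 3L), theta = rep(bank$theta, 3L))
  mu <- colMeans(feats)
  sdv <- col_sd_pop(feats)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    abort(sprintf("zero-variance feature(s) across the stimulus set: %s%s",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else ""))
  }
  feats <- sweep(sweep(feats, 2L, mu, `-`), 2L, sdv, `/`)
  structure(feats, class = c("gabor_features", class(feats)), metadata = meta)
}

#' Wrap predicted responses as a response set
#'
#' Convenience for feeding encoding-model predictions (stimuli × channels)
#' back into the cross-decomposition pipeline.
#'
#' @param predictions Numeric matrix, stimuli × channels.
#' @param template A [response_set()] supplying identifiers/metadata.
#' @param trial_index Trial index to record (default: template's).
#' @return A [response_set()].
#' @export
predictions_as_response_set <- function(predictions, template,
                                        trial_index = template$trial_index) {
  stopifnot(inherits(template, "response_set"))
  response_set(predictions, stimulus_ids = template$stimulus_ids,
               channel_ids = template$channel_ids,
               subject_id = template$subject_id, region_id = template$region_id,
               trial_index = trial_index)
}

#' Cross-decomposition of measured vs model-predicted responses
#'
#' Runs the cross-validated spectral estimator between measured responses
#' (one trial) and encoding-model predictions of another trial, then bins,
#' aggregates, and summarizes the normalized cumulative shared variance
#' (running sum of the positive binned contributions over their total). A
#' low-rank model saturates its cumulative curve at much lower rank than
#' the measured data.
#'
#' @param neural A [response_set()] of measured responses.
#' @param predicted A [response_set()] of model-predicted responses with
#'   the neural channel dimensionality.
#' @param folds A [make_folds()] plan.
#' @param scheme A [make_log_bins()] scheme.
#' @return A list with `spectrum` (a `binned_spectrum`) and `cumulative`
#'   (tibble `bin`, `bin_center`, `cumulative` in `[0, 1]`).
#' @export
model_vs_neural_spectrum <- function(neural, predicted, folds, scheme) {
  spec <- within_system_spectrum(neural, predicted, folds)
  bs <- aggregate_folds(bin_spectrum(spec, scheme))
  contrib <- pmax(bs$mean, 0) * bs$n_ranks
  cum <- tibble(bin = bs$bin, bin_center = bs$bin_center,
                cumulative = cumsum(contrib) / sum(contrib))
  list(spectrum = bs, cumulative = cum)
}
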