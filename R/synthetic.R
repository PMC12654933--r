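#' Configuration for the synthetic scale-free ensemble
#'
#' Defines a multi-subject, multi-trial population-response model with
#' known ground truth: shared zero-mean Gaussian latent signals whose
#' variances decay as a power law in rank (`lambda_k` proportional to
#' `k^-alpha`, normalized to sum to `n_latent`), subject-specific
#' orthonormal channel embeddings (optionally with a leading block of
#' anatomically shared columns), independent additive white trial noise,
#' and per-channel z-scoring. The defaults emulate the structure of a
#' two-subject, two-trial natural-scenes fMRI comparison: 766 shared
#' stimuli, an exponent of 1.6, fully shared latents, and unit-scale
#' noise against per-channel signal of order one.
#'
#' @param n_subjects Number of subjects (default 2).
#' @param n_trials Trial repetitions per subject (default 2).
#' @param n_stimuli Number of stimuli (default 766).
#' @param n_channels Channels (voxels/units) per subject (default 512).
#' @param n_latent Number of latent signal dimensions `K_true`
#'   (default `n_channels`).
#' @param alpha Power-law exponent of latent variances (default 1.6).
#' @param shared_fraction Portion of each latent's variance common to all
#'   subjects, in `[0, 1]` (default 1). Private latents reuse the same
#'   variance profile, so this equals the expected spectral correlation.
#' @param n_aligned_latents Leading latents whose channel loadings are
#'   identical across subjects (default 0: purely functional alignment).
#' @param noise_sd Standard deviation of the additive per-trial channel
#'   noise (default 1).
#' @param zscore Z-score each generated trial's channels over all stimuli
#'   (default `TRUE`, emulating standard preprocessing). Set `FALSE` to
#'   obtain exact rotated copies for algebraic checks.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 2L, n_trials = 2L, n_stimuli = 766L,
                         n_channels = 512L, n_latent = n_channels,
                         alpha = 1.6, shared_fraction = 1,
                         n_aligned_latents = 0L, noise_sd = 1,
                         zscore = TRUE, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
              n_stimuli = as.integer(n_stimuli), n_channels = as.integer(n_channels),
              n_latent = as.integer(n_latent), alpha = alpha,
              shared_fraction = shared_fraction,
              n_aligned_latents = as.integer(n_aligned_latents),
              noise_sd = noise_sd, zscore = isTRUE(zscore), seed = as.integer(seed))
  if (cfg$n_latent > cfg$n_channels) abort("`n_latent` cannot exceed `n_channels`")
  if (cfg$n_aligned_latents > cfg$n_latent) abort("`n_aligned_latents` cannot exceed `n_latent`")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) abort("`shared_fraction` must be in [0, 1]")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be nonnegative")
  if (cfg$n_stimuli < 2L || cfg$n_subjects < 1L || cfg$n_trials < 1L) {
    abort("need at least 2 stimuli and 1 subject/trial")
  }
  structure(cfg, class = "synth_config")
}

## ground-truth latent variances: lambda_k ~ k^-alpha, sum = n_latent
latent_variances <- function(cfg) {
  lam <- seq_len(cfg$n_latent)^(-cfg$alpha)
  lam / sum(lam) * cfg$n_latent
}

#' Generate a synthetic multi-subject response ensemble
#'
#' Draws the model defined by [synth_config()]: each subject's latent
#' trajectory mixes a common draw (weight `sqrt(shared_fraction)`) with a
#' private draw (weight `sqrt(1 - shared_fraction)`), both with variances
#' `lambda_k`; responses are `latents %*% t(embedding)` plus independent
#' white noise per trial; channels are then z-scored per trial (population
#' sd) unless `zscore = FALSE`. Embeddings are random orthonormal
#' `n_channels x n_latent` matrices whose first `n_aligned_latents` columns
#' are identical across subjects.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synthetic_ensemble` with `responses` (nested
#'   list: `responses[[subject]][[trial]]` is a [response_set()]) and
#'   `ground_truth` (`lambda`, per-subject `embeddings`, `noise_sd`, the
#'   config).
#' @examples
#' ens <- generate_ensemble(synth_config(n_stimuli = 64, n_channels = 16, seed = 2))
#' ens$responses[[1]][[1]]
#' @export
generate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lam <- latent_variances(cfg)
  n <- cfg$n_stimuli; d <- cfg$n_channels; k <- cfg$n_latent
  stim <- sprintf("s%05d", seq_len(n))
  chan <- sprintf("ch%05d", seq_len(d))
  out <- withr::with_seed(cfg$seed, {
    z_shared <- matrix(rnorm(n * k), n, k)
    aligned_block <- if (cfg$n_aligned_latents > 0) {
      matrix(rnorm(d * cfg$n_aligned_latents), d, cfg$n_aligned_latents)
    } else NULL
    embeddings <- lapply(seq_len(cfg$n_subjects), function(s) {
      m <- matrix(rnorm(d * k), d, k)
      if (!is.null(aligned_block)) m[, seq_len(cfg$n_aligned_latents)] <- aligned_block
      qr.Q(qr(m))[, seq_len(k), drop = FALSE]
    })
    responses <- lapply(seq_len(cfg$n_subjects), function(s) {
      z_priv <- matrix(rnorm(n * k), n, k)
      z <- sqrt(cfg$shared_fraction) * z_shared +
        sqrt(1 - cfg$shared_fraction) * z_priv
      z <- sweep(z, 2L, sqrt(lam), `*`)
      lapply(seq_len(cfg$n_trials), function(tr) {
        x <- z %*% t(embeddings[[s]])
        if (cfg$noise_sd > 0) x <- x + cfg$noise_sd * matrix(rnorm(n * d), n, d)
        rs <- response_set(x, stimulus_ids = stim, channel_ids = chan,
                           subject_id = sprintf("subject%d", s),
                           trial_index = tr)
        if (cfg$zscore) rs <- zscore_channels(rs) else rs
      })
    })
    list(responses = responses, embeddings = embeddings)
  })
  structure(
    list(responses = out$responses,
         ground_truth = list(lambda = lam, embeddings = out$embeddings,
                             noise_sd = cfg$noise_sd, config = cfg)),
    class = "synthetic_ensemble"
  )
}

#' Closed-form expected spectra for a synthetic configuration
#'
#' The expected within-subject cross-trial spectrum is the latent signal
#' variance `lambda_k` (trial noise is independent across trials and
#' cancels in expectation), and the expected between-subject spectrum is
#' `shared_fraction * lambda_k`; both are zero beyond `n_latent`.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with columns `rank`, `within`, `between`.
#' @export
expected_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lam <- latent_variances(cfg)
  tibble(rank = seq_len(cfg$n_latent), within = lam,
         between = cfg$shared_fraction * lam)
}

#' Procedural test images
#'
#' Deterministic (seeded) square grayscale image stacks for exercising the
#' Gabor feature pipeline without natural images: oriented sinusoidal
#' gratings with random orientation, frequency and phase, or band-limited
#' Gaussian noise (white noise filtered to an annulus of spatial
#' frequencies).
#'
#' @param kind `"gratings"` or `"bandlimited-noise"`.
#' @param count Number of images.
#' @param resolution Image side in pixels.
#' @param seed Integer seed.
#' @param freq_range Spatial-frequency range, cycles per image side
#'   (gratings: sampled uniformly; noise: annulus pass band).
#' @return A `count` × `resolution` × `resolution` array; for gratings the
#'   sampled parameters are attached as attribute `params` (a tibble).
#' @export
generate_test_images <- function(kind = c("gratings", "bandlimited-noise"),
                                 count, resolution, seed = 1L,
                                 freq_range = c(2, 8)) {
  kind <- match.arg(kind)
  count <- as.integer(count); resolution <- as.integer(resolution)
  if (count < 1L || resolution < 8L) abort("need count >= 1 and resolution >= 8")
  g <- seq(-0.5 + 0.5 / resolution, 0.5 - 0.5 / resolution, length.out = resolution)
  xm <- matrix(g, resolution, resolution, byrow = TRUE)
  ym <- matrix(g, resolution, resolution)
  withr::with_seed(as.integer(seed), {
    imgs <- array(0, dim = c(count, resolution, resolution))
    if (kind == "gratings") {
      theta <- stats::runif(count, 0, pi)
      freq <- stats::runif(count, freq_range[1], freq_range[2])
      phase <- stats::runif(count, 0, 2 * pi)
      for (i in seq_len(count)) {
        imgs[i, , ] <- sin(2 * pi * freq[i] * (xm * cos(theta[i]) + ym * sin(theta[i])) + phase[i])
      }
      attr(imgs, "params") <- tibble(theta = theta, freq = freq, phase = phase)
    } else {
      fr <- sqrt(outer(fft_freqs(resolution)^2, fft_freqs(resolution)^2, `+`))
      mask <- fr >= freq_range[1] & fr <= freq_range[2]
      for (i in seq_len(count)) {
        w <- matrix(rnorm(resolution^2), resolution)
        filt <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / resolution^2
        imgs[i, , ] <- filt / stats::sd(filt)
      }
    }
    imgs
  })
}

## FFT frequency magnitudes in cycles per image side
fft_freqs <- function(n) {
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1))
  f[seq_len(n)]
}
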