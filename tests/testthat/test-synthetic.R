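test_that("configs validate their invariants", {
  expect_error(synth_config(n_channels = 8, n_latent = 16), "n_latent")
  expect_error(synth_config(n_latent = 4, n_aligned_latents = 5), "n_aligned")
  expect_error(synth_config(shared_fraction = 1.2), "shared_fraction")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("embeddings are orthonormal and share the aligned leading block", {
  cfg <- synth_config(n_subjects = 3, n_stimuli = 40, n_channels = 20,
                      n_latent = 12, n_aligned_latents = 5, seed = 2)
  ens <- generate_ensemble(cfg)
  embs <- ens$ground_truth$embeddings
  for (e in embs) {
    expect_equal(crossprod(e), diag(12), tolerance = 1e-10)
  }
  # the first 5 columns coincide across subjects; the rest differ
  expect_equal(embs[[1]][, 1:5], embs[[2]][, 1:5], tolerance = 1e-12)
  expect_equal(embs[[2]][, 1:5], embs[[3]][, 1:5], tolerance = 1e-12)
  expect_gt(max(abs(embs[[1]][, 6:12] - embs[[2]][, 6:12])), 1e-3)
})

test_that("latent variances follow the power law and sum to n_latent", {
  cfg <- synth_config(n_stimuli = 16, n_channels = 8, alpha = 1.6, seed = 1)
  lam <- expected_spectra(cfg)$within
  expect_equal(sum(lam), 8, tolerance = 1e-12)
  expect_equal(lam / lam[1], (1:8)^-1.6, tolerance = 1e-12)
  # flat spectrum at alpha = 0
  flat <- expected_spectra(synth_config(n_stimuli = 16, n_channels = 8, alpha = 0))
  expect_true(all(flat$within == 1))
  # between = shared_fraction * within
  half <- expected_spectra(synth_config(n_stimuli = 16, n_channels = 8,
                                        shared_fraction = 0.5))
  expect_equal(half$between, 0.5 * half$within, tolerance = 1e-12)
})

test_that("generation is deterministic given the seed and varies across seeds", {
  cfg <- synth_config(n_stimuli = 32, n_channels = 8, seed = 9)
  a <- generate_ensemble(cfg)
  b <- generate_ensemble(cfg)
  expect_identical(a$responses[[1]][[1]]$values, b$responses[[1]][[1]]$values)
  c_ <- generate_ensemble(synth_config(n_stimuli = 32, n_channels = 8, seed = 10))
  expect_false(identical(a$responses[[1]][[1]]$values,
                         c_$responses[[1]][[1]]$values))
})

test_that("empirical binned spectra approach the closed-form expectations", {
  cfg <- synth_config(n_subjects = 2, n_stimuli = 768, n_channels = 64,
                      noise_sd = 0.2, zscore = FALSE, seed = 21)
  ens <- generate_ensemble(cfg)
  folds <- make_folds(ens$responses[[1]][[1]]$stimulus_ids, 8, seed = 1)
  scheme <- make_log_bins(1, 64, 2.75)
  lam_binned <- tapply(expected_spectra(cfg)$within / 64,
                       bin_membership(scheme, 1:64), mean)
  # bins near the rank limit are excluded: learned directions there mix
  # quasi-degenerate latents, a known boundary bias of spectral estimators
  core <- which(scheme$upper <= 32)
  w <- aggregate_folds(bin_spectrum(
    within_system_spectrum(ens$responses[[1]][[1]], ens$responses[[1]][[2]], folds),
    scheme))
  expect_true(all(abs(w$mean - lam_binned)[core] <= (3 * w$sd)[core]))
  b <- aggregate_folds(bin_spectrum(
    between_system_spectrum(ens$responses[[1]][[1]], ens$responses[[1]][[2]],
                            ens$responses[[2]][[1]], ens$responses[[2]][[2]], folds),
    scheme))
  expect_true(all(abs(b$mean - lam_binned)[core] <= (3 * b$sd)[core]))
})

test_that("unshared subjects produce a between spectrum consistent with the null", {
  cfg <- synth_config(n_subjects = 2, n_stimuli = 256, n_channels = 32,
                      shared_fraction = 0, noise_sd = 0.5, seed = 22)
  ens <- generate_ensemble(cfg)
  x <- ens$responses[[1]]; y <- ens$responses[[2]]
  folds <- make_folds(x[[1]]$stimulus_ids, 8, seed = 2)
  scheme <- make_log_bins(1, 32, 2.75)
  obs <- aggregate_folds(bin_spectrum(
    between_system_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds), scheme))
  nul <- build_null_ensemble(x[[1]], x[[2]], folds, scheme, n_perms = 499,
                             seed = 3, y1 = y[[1]], y2 = y[[2]], mode = "between")
  expect_false(any(flag_significance(obs, nul, alpha = 0.01)$significant))
})

test_that("the within-subject exponent is recovered at moderate size", {
  ens <- generate_ensemble(synth_config(n_subjects = 1, n_stimuli = 1024,
                                        n_channels = 256, alpha = 1.6,
                                        noise_sd = 0.25, seed = 23))
  folds <- make_folds(ens$responses[[1]][[1]]$stimulus_ids, 8, seed = 4)
  scheme <- make_log_bins(1, 256, 2.75)
  bs <- aggregate_folds(bin_spectrum(
    within_system_spectrum(ens$responses[[1]][[1]], ens$responses[[1]][[2]], folds),
    scheme))
  fit <- fit_power_law(bs, fit_range = c(1, 100))
  expect_lt(abs(fit$exponent - (-1.6)), 0.15)
})

test_that("anatomical alignment detects only the aligned leading latents", {
  # 10 anatomically aligned latents: the anatomical spectrum loses
  # significance beyond the bin containing rank 10 while the functional
  # spectrum stays significant beyond it. Bins are kept wide (2/decade) so
  # that finite-sample mixing among quasi-degenerate singular pairs at the
  # alignment boundary stays inside the rank-10 bin.
  ens <- cached("aligned10", generate_ensemble(
    synth_config(n_subjects = 2, n_stimuli = 1024, n_channels = 256,
                 n_aligned_latents = 10, noise_sd = 1, seed = 24)))
  x <- ens$responses[[1]]; y <- ens$responses[[2]]
  folds <- make_folds(x[[1]]$stimulus_ids, 8, seed = 5)
  scheme <- make_log_bins(1, 256, 2)
  rank10_bin <- bin_membership(scheme, 10L)

  ana <- aggregate_folds(bin_spectrum(
    anatomical_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds), scheme))
  nul_a <- build_null_ensemble(x[[1]], x[[2]], folds, scheme, n_perms = 300,
                               seed = 6, y1 = y[[1]], y2 = y[[2]],
                               mode = "anatomical")
  fa <- flag_significance(ana, nul_a, alpha = 0.01)
  expect_false(any(fa$significant[fa$bin > rank10_bin]))
  expect_true(any(fa$significant[fa$bin <= rank10_bin]))

  fun <- aggregate_folds(bin_spectrum(
    between_system_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds), scheme))
  nul_f <- build_null_ensemble(x[[1]], x[[2]], folds, scheme, n_perms = 300,
                               seed = 7, y1 = y[[1]], y2 = y[[2]],
                               mode = "between")
  ff <- flag_significance(fun, nul_f, alpha = 0.01)
  expect_true(any(ff$significant[ff$bin > rank10_bin]))
})

test_that("procedural images are deterministic and gratings drive matched filters", {
  g1 <- generate_test_images("gratings", 6, 32, seed = 3)
  g2 <- generate_test_images("gratings", 6, 32, seed = 3)
  expect_identical(g1, g2)
  nz <- generate_test_images("bandlimited-noise", 4, 32, seed = 3)
  expect_identical(dim(nz), c(4L, 32L, 32L))
  expect_error(generate_test_images("swirls", 4, 32), "arg")

  # a theta = 0 grating at matched frequency concentrates energy responses
  # in the theta = 0 filters (checked via the gabor module)
  cfg <- gabor_bank_config(scales = 0.12, freq_mult = 0.6, n_orientations = 4,
                           grid_n = 2, frequency_convention = "divide",
                           resolution = 32)
  bank <- build_gabor_bank(cfg)   # f = 5 cycles/image
  filler <- generate_test_images("bandlimited-noise", 20, 32, seed = 4,
                                 freq_range = c(3, 7))
  g <- seq(-0.5 + 1 / 64, 0.5 - 1 / 64, length.out = 32)
  grating0 <- sin(2 * pi * 5 * matrix(g, 32, 32, byrow = TRUE))
  stack <- array(0, c(21, 32, 32))
  stack[1, , ] <- grating0
  stack[2:21, , ] <- filler
  feats <- extract_gabor_features(stack, bank)
  meta <- attr(feats, "metadata")
  en <- meta$kind == "energy"
  by_theta <- tapply(feats[1, en], meta$theta[en], mean)
  expect_identical(names(which.max(by_theta)), "0")
})
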