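test_that("self-decomposition of orthogonal columns is the eigendecomposition", {
  # centered, orthogonal columns with population variances 4 and 1
  a <- cbind(2 * c(1, 1, -1, -1), c(1, -1, 1, -1))
  basis <- fit_cross_basis(a, a)
  expect_equal(basis$sigma_train, c(4, 1), tolerance = 1e-10)
  expect_equal(abs(basis$u), diag(2), tolerance = 1e-10)
  expect_equal(basis$u, basis$v, tolerance = 1e-10)
})

test_that("fit/evaluate match the brute-force SVD + diagonal assembly oracle", {
  for (i in 1:25) {
    withr::with_seed(100 + i, {
      dx <- sample(2:6, 1); dy <- sample(2:6, 1); n <- sample(8:16, 1)
      tr_a <- matrix(rnorm(n * dx), n); tr_b <- matrix(rnorm(n * dy), n)
      te_a <- matrix(rnorm(10 * dx), 10); te_b <- matrix(rnorm(10 * dy), 10)
    })
    want <- oracle_cross_spectrum(tr_a, tr_b, te_a, te_b)
    basis <- fit_cross_basis(tr_a, tr_b)
    expect_equal(basis$sigma_train, want$sigma_train, tolerance = 1e-10)
    got <- evaluate_test_spectrum(basis, te_a, te_b)
    expect_equal(got$value, want$spectrum, tolerance = 1e-10)
  }
})

test_that("orthonormality, ordering and the in-sample identity hold", {
  withr::with_seed(2, {
    a <- matrix(rnorm(12 * 3), 12); b <- matrix(rnorm(12 * 4), 12)
  })
  basis <- fit_cross_basis(a, b)
  expect_equal(crossprod(basis$u), diag(basis$k), tolerance = 1e-8)
  expect_equal(crossprod(basis$v), diag(basis$k), tolerance = 1e-8)
  expect_true(all(diff(basis$sigma_train) <= 1e-12))
  # test = train reproduces the training singular values exactly
  expect_equal(evaluate_test_spectrum(basis, a, b)$value, basis$sigma_train,
               tolerance = 1e-10)
})

test_that("a column-permuted copy gives the same spectrum with permuted V", {
  withr::with_seed(3, a <- matrix(rnorm(14 * 5), 14))
  perm <- c(3, 1, 5, 2, 4)
  self <- fit_cross_basis(a, a)
  permd <- fit_cross_basis(a, a[, perm])
  expect_equal(permd$sigma_train, self$sigma_train, tolerance = 1e-10)
  expect_equal(permd$v, permd$u[perm, ], tolerance = 1e-10)
})

test_that("degenerate inputs are handled: tiny n errors, zero cross-cov does not", {
  expect_error(fit_cross_basis(matrix(1, 1, 2), matrix(1, 1, 2)), "at least 2")
  z <- matrix(0, 6, 3)
  withr::with_seed(4, a <- matrix(rnorm(18), 6))
  basis <- fit_cross_basis(a, z)
  expect_equal(basis$sigma_train, rep(0, basis$k))
  withr::with_seed(5, bad <- matrix(rnorm(12), 6, 2))
  expect_error(evaluate_test_spectrum(basis, a, bad), "mismatch")
})

test_that("shuffled test rows give a spectrum with mean zero per rank", {
  withr::with_seed(6, {
    tr_a <- matrix(rnorm(40 * 4), 40); tr_b <- tr_a + matrix(rnorm(40 * 4), 40)
    te_a <- matrix(rnorm(12 * 4), 12); te_b <- te_a + matrix(rnorm(12 * 4), 12)
  })
  basis <- fit_cross_basis(tr_a, tr_b)
  draws <- withr::with_seed(7, {
    vapply(1:1000, function(i) {
      permuted_spectrum(basis, te_a, te_b, sample.int(12))$value
    }, numeric(basis$k))
  })
  m <- rowMeans(draws); se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(m) <= 3 * se))
})

test_that("off-diagonal mass is zero in-sample, small in-distribution, ~1 for noise", {
  withr::with_seed(8, {
    a <- matrix(rnorm(60 * 5), 60); b <- a %*% matrix(rnorm(25), 5) + 0.3 * matrix(rnorm(60 * 5), 60)
  })
  basis <- fit_cross_basis(a, b)
  expect_lt(offdiagonal_mass(basis, a, b), 1e-10)

  ratio_at <- function(n) {
    withr::with_seed(n, {
      lam <- sqrt((1:5)^-1.6)
      z_tr <- matrix(rnorm(n * 5), n) ; z_te <- matrix(rnorm(400 * 5), 400)
      ea <- qr.Q(qr(matrix(rnorm(64 * 5), 64)))
      eb <- qr.Q(qr(matrix(rnorm(64 * 5), 64)))
      mk <- function(z) sweep(z, 2, lam, `*`)
      tr_a <- mk(z_tr) %*% t(ea) + 0.2 * matrix(rnorm(n * 64), n)
      tr_b <- mk(z_tr) %*% t(eb) + 0.2 * matrix(rnorm(n * 64), n)
      te_a <- mk(z_te) %*% t(ea) + 0.2 * matrix(rnorm(400 * 64), 400)
      te_b <- mk(z_te) %*% t(eb) + 0.2 * matrix(rnorm(400 * 64), 400)
    })
    offdiagonal_mass(fit_cross_basis(tr_a, tr_b), te_a, te_b)
  }
  r <- vapply(c(100, 400, 1600), ratio_at, numeric(1))
  expect_true(all(diff(r) < 0))   # shrinks with training size

  withr::with_seed(9, indep <- matrix(rnorm(60 * 5), 60))
  expect_gt(offdiagonal_mass(basis, a, indep), 0.8)
})

test_that("normalization divides by the geometric mean of channel counts once", {
  s <- crossdecomp:::new_fold_spectrum(1:3, c(2, 1, 0.5))
  expect_equal(normalize_by_channels(s, 10, 10)$value, c(2, 1, 0.5) / 10)
  expect_equal(normalize_by_channels(s, 100, 400)$value, c(2, 1, 0.5) / 200)
  expect_error(normalize_by_channels(normalize_by_channels(s, 10, 10), 10, 10),
               "already")
})

test_that("spectra are scale-equivariant and the between estimator is rotation-invariant", {
  p <- small_pair(n = 64, d = 12, noise_sd = 0.3, seed = 21)
  folds <- make_folds(p$x1$stimulus_ids, 4, seed = 1)
  withr::with_seed(22, {
    q <- small_pair(n = 64, d = 12, noise_sd = 0.3, seed = 23)
  })
  base <- between_system_spectrum(p$x1, p$x2, q$x1, q$x2, folds)

  # scale: multiply one side by c (before channel normalization it scales by c;
  # channel counts are unchanged so the normalized spectrum scales by c too)
  scale_rs <- function(rs, c) response_set(rs$values * c, rs$stimulus_ids,
                                           rs$channel_ids)
  scaled <- between_system_spectrum(scale_rs(p$x1, 3), scale_rs(p$x2, 3),
                                    q$x1, q$x2, folds)
  expect_equal(scaled$value, 3 * base$value, tolerance = 1e-10)

  # rotation: right-multiplying either system by an orthonormal matrix
  withr::with_seed(24, rot <- qr.Q(qr(matrix(rnorm(144), 12))))
  rot_rs <- function(rs) response_set(rs$values %*% rot, rs$stimulus_ids,
                                      rs$channel_ids)
  rotated <- between_system_spectrum(p$x1, p$x2, rot_rs(q$x1), rot_rs(q$x2), folds)
  expect_equal(rotated$value, base$value, tolerance = 1e-8)
})

test_that("within-system spectrum per fold matches a brute-force fold loop", {
  p <- small_pair(n = 48, d = 10, noise_sd = 0.4, seed = 31)
  folds <- make_folds(p$x1$stimulus_ids, 4, seed = 2)
  got <- within_system_spectrum(p$x1, p$x2, folds)
  ids <- sort(p$x1$stimulus_ids, method = "radix")
  v1 <- p$x1$values[ids, ]; v2 <- p$x2$values[ids, ]
  f <- folds$fold[match(ids, folds$stimulus_id)]
  for (ff in 1:4) {
    want <- oracle_cross_spectrum(v1[f != ff, ], v2[f != ff, ],
                                  v1[f == ff, ], v2[f == ff, ])
    expect_equal(got$value[got$fold == ff], want$spectrum / 10, tolerance = 1e-10)
  }
})

test_that("noise-free same-trial decomposition gives nonnegative spectra", {
  ens <- generate_ensemble(synth_config(n_subjects = 1, n_trials = 1,
                                        n_stimuli = 60, n_channels = 12,
                                        noise_sd = 0, zscore = FALSE, seed = 41))
  x <- ens$responses[[1]][[1]]
  folds <- make_folds(x$stimulus_ids, 4, seed = 3)
  s <- within_system_spectrum(x, x, folds)
  expect_true(all(s$value >= -1e-12))
})

test_that("between-system reduces to within for identical systems and is trial-symmetric", {
  p <- small_pair(n = 64, d = 12, seed = 51)
  folds <- make_folds(p$x1$stimulus_ids, 4, seed = 4)
  w <- within_system_spectrum(p$x1, p$x2, folds)
  # Y trials identical copies of X trials: the symmetrized average of
  # S(x1, x2) and S(x2, x1) equals the within spectrum (transposing the
  # cross-covariance exchanges U and V but leaves the spectrum unchanged)
  b_same <- between_system_spectrum(p$x1, p$x2, p$x1, p$x2, folds)
  expect_equal(b_same$value, w$value, tolerance = 1e-10)
  # swapping trial labels in both systems leaves the estimate unchanged
  b_swap <- between_system_spectrum(p$x2, p$x1, p$x2, p$x1, folds)
  expect_equal(b_swap$value, b_same$value, tolerance = 1e-12)
  expect_equal(dim(b_same), dim(w))
})

test_that("noise-free rotated-copy subjects: between equals within exactly", {
  ens <- generate_ensemble(synth_config(n_subjects = 2, n_stimuli = 96,
                                        n_channels = 16, noise_sd = 0,
                                        zscore = FALSE, seed = 61))
  x <- ens$responses[[1]]; y <- ens$responses[[2]]
  folds <- make_folds(x[[1]]$stimulus_ids, 4, seed = 5)
  w <- within_system_spectrum(x[[1]], x[[2]], folds)
  b <- between_system_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds)
  expect_equal(b$value, w$value, tolerance = 1e-8)
})

test_that("anatomical projection swap: aligned channels agree, permuted channels collapse", {
  # identical embeddings for all subjects: anatomical == functional
  ens <- generate_ensemble(synth_config(n_subjects = 2, n_stimuli = 96,
                                        n_channels = 16, n_aligned_latents = 16,
                                        noise_sd = 0, zscore = FALSE, seed = 71))
  x <- ens$responses[[1]]; y <- ens$responses[[2]]
  folds <- make_folds(x[[1]]$stimulus_ids, 4, seed = 6)
  fun <- between_system_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds)
  ana <- anatomical_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds)
  expect_equal(ana$value, fun$value, tolerance = 1e-8)

  # channel-permuted copy: functional unchanged, anatomical consistent with 0
  p <- small_pair(n = 96, d = 16, noise_sd = 0.3, seed = 72)
  perm <- withr::with_seed(73, sample(16))
  permute_channels <- function(rs) response_set(rs$values[, perm], rs$stimulus_ids,
                                                rs$channel_ids)
  y1p <- permute_channels(p$x1); y2p <- permute_channels(p$x2)
  folds2 <- make_folds(p$x1$stimulus_ids, 4, seed = 7)
  fun2 <- between_system_spectrum(p$x1, p$x2, y1p, y2p, folds2)
  fun0 <- between_system_spectrum(p$x1, p$x2, p$x1, p$x2, folds2)
  expect_equal(fun2$value, fun0$value, tolerance = 1e-8)
  ana2 <- anatomical_spectrum(p$x1, p$x2, y1p, y2p, folds2)
  scheme <- make_log_bins(1, 16, 3)
  agg <- aggregate_folds(bin_spectrum(ana2, scheme))
  nul <- build_null_ensemble(p$x1, p$x2, folds2, scheme, n_perms = 300, seed = 74,
                             y1 = y1p, y2 = y2p, mode = "anatomical")
  expect_false(any(flag_significance(agg, nul, alpha = 0.01)$significant))

  odd <- response_set(p$x1$values[, 1:15], p$x1$stimulus_ids,
                      p$x1$channel_ids[1:15])
  expect_error(anatomical_spectrum(p$x1, p$x2, odd, odd, folds2), "common channel")
})

test_that("PCA matches an eigen oracle and self-decomposition reproduces it", {
  withr::with_seed(81, m <- matrix(rnorm(40), 10, 4))
  ev <- eigen(crossprod(scale(m, scale = FALSE)) / 10, symmetric = TRUE)$values
  expect_equal(pca_spectrum(m)$value, ev[1:4], tolerance = 1e-10)
  basis <- fit_cross_basis(m, m)
  expect_equal(basis$sigma_train, ev[1:4], tolerance = 1e-10)
})

test_that("PCA >= cvPCA at low rank and cvPCA >= cross-decomposition at high rank", {
  p <- small_pair(n = 256, d = 32, noise_sd = 1, seed = 91)
  # noise-free identical trials: all three coincide
  ens0 <- generate_ensemble(synth_config(n_subjects = 1, n_stimuli = 128,
                                         n_channels = 16, noise_sd = 0,
                                         zscore = FALSE, seed = 92))
  x0 <- ens0$responses[[1]][[1]]
  expect_equal(cvpca_spectrum(x0, x0)$value, pca_spectrum(x0)$value,
               tolerance = 1e-8)

  pca <- pca_spectrum(p$x1)$value
  cvp <- cvpca_spectrum(p$x1, p$x2)$value
  folds <- make_folds(p$x1$stimulus_ids, 8, seed = 8)
  cd <- aggregate_folds(bin_spectrum(within_system_spectrum(p$x1, p$x2, folds),
                                     make_log_bins(1, 32, 3)))
  # PCA keeps signal + noise: above cvPCA at low ranks
  expect_true(all(pca[1:5] >= cvp[1:5]))
  # cvPCA needs no generalization to new stimuli: above cross-decomposition
  # in the noise-dominated tail (compare in the same normalized units)
  tail_bins <- cd$bin_center > 8
  cvp_binned <- tapply(cvp / 32, crossdecomp::bin_membership(make_log_bins(1, 32, 3), 1:32), mean)
  expect_true(all(cvp_binned[tail_bins] > cd$mean[tail_bins]))
})
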