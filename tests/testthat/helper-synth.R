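# Shared fixtures, built in code. Heavier ensembles are cached per session
# (test files run in one process, helpers are loaded once).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

rand_rs <- function(n, d, seed = 1, subject = "subject1", trial = 1L) {
  withr::with_seed(seed, {
    response_set(matrix(rnorm(n * d), n, d),
                 stimulus_ids = sprintf("s%04d", seq_len(n)),
                 channel_ids = sprintf("ch%03d", seq_len(d)),
                 subject_id = subject, trial_index = trial)
  })
}

## brute-force assembly of the aligned basis + test spectrum, kept
## deliberately independent of the package internals: explicit centering,
## base svd of the fully assembled cross-covariance, explicit diagonal of
## t(U) %*% C_test %*% V with mean-subtracted population covariance.
oracle_cross_spectrum <- function(train_a, train_b, test_a, test_b) {
  ctr <- function(m, mu) m - rep(1, nrow(m)) %*% t(mu)
  ma <- colMeans(train_a); mb <- colMeans(train_b)
  c_train <- t(ctr(train_a, ma)) %*% ctr(train_b, mb) / nrow(train_a)
  k <- min(ncol(train_a), ncol(train_b), nrow(train_a) - 1)
  sv <- svd(c_train)
  u <- sv$u[, 1:k, drop = FALSE]; v <- sv$v[, 1:k, drop = FALSE]
  ta <- ctr(test_a, ma); tb <- ctr(test_b, mb)
  pa <- ta %*% u; pb <- tb %*% v
  pa <- ctr(pa, colMeans(pa)); pb <- ctr(pb, colMeans(pb))
  c_test <- t(pa) %*% pb / nrow(test_a)
  list(sigma_train = sv$d[1:k], spectrum = diag(c_test), u = u, v = v)
}

## two small trials with shared power-law signal
small_pair <- function(n = 96, d = 24, noise_sd = 0.5, seed = 7, ...) {
  ens <- generate_ensemble(synth_config(n_subjects = 1, n_stimuli = n,
                                        n_channels = d, noise_sd = noise_sd,
                                        seed = seed, ...))
  list(x1 = ens$responses[[1]][[1]], x2 = ens$responses[[1]][[2]], ens = ens)
}
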