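## Orchestration: configured end-to-end runs writing figure-ready CSVs.
## A run config is a plain named list (or a YAML file of one); all
## randomness flows from two named seeds (folds, permutations/bootstrap),
## and every output embeds the config hash and the seeds.

default_run_config <- function() {
  list(
    inputs = NULL,            # list of response_sets, or named file paths
    mode = "within",          # within | between | anatomical
    estimator = "crossdecomp",# crossdecomp | pca | cvpca
    n_folds = 8L,
    seed_folds = 1L,
    bin_k_min = 1L, bin_k_max = NULL, bin_per_decade = 2.75,
    normalize = TRUE,
    n_perms = 0L,             # 0 = skip null
    seed_perms = 1L,
    alpha = 0.001,
    fit_range = NULL,         # rank interval for the power-law fit
    wide_per_decade = 2,      # r_k bins
    n_boot = 5000L, rsa_fraction = 0.9, rsa_components = 10L,
    output_dir = NULL
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or a YAML file path")
  cfg <- modifyList(default_run_config(), config)
  cfg
}

resolve_inputs <- function(cfg, n_required) {
  ins <- cfg$inputs
  if (is.null(ins)) abort("config must provide `inputs`")
  ins <- lapply(ins, function(x) {
    if (inherits(x, "response_set")) x else read_response_set(x)
  })
  if (length(ins) < n_required) {
    abort(sprintf("this analysis needs %d input response sets, got %d",
                  n_required, length(ins)))
  }
  ## fail early on inconsistent stimulus sets
  ids <- stim_ids(ins[[1]])
  for (x in ins[-1]) {
    if (!setequal(ids, stim_ids(x))) abort("inputs cover inconsistent stimulus sets")
  }
  ins
}

config_stamp <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), c("inputs", "output_dir"))]
  list(config_hash = rlang::hash(flat),
       seed_folds = cfg$seed_folds, seed_perms = cfg$seed_perms)
}

write_run_log <- function(cfg, stamp, path, extra = list()) {
  log <- c(stamp, cfg[setdiff(names(cfg), "inputs")], extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

stage_msg <- function(stage, ..., t0 = NULL) {
  timing <- if (!is.null(t0)) sprintf(" [%.2fs]", as.numeric(Sys.time()) - t0) else ""
  message(sprintf("[%s] %s%s", stage, paste0(...), timing))
}

#' Run a configured spectrum analysis end to end
#'
#' Computes the configured cross-validated spectrum (within-, between-, or
#' anatomically aligned, or the PCA/cvPCA comparison estimators), bins and
#' fold-averages it, optionally calibrates a permutation null and flags
#' per-bin significance, and fits a power law. When `output_dir` is set,
#' writes `spectrum.csv`, `null_percentiles.csv` (if requested),
#' `power_law.csv`, and `run_log.json` (all parameters, seeds and the
#' config hash); reruns with the same config produce identical files.
#'
#' @param config A named list (see Details in the package vignette) or the
#'   path of a YAML file. `inputs` must hold 2 (within), or 4 (between /
#'   anatomical) response sets or file paths, ordered x1, x2, y1, y2.
#' @return A list with `spectrum` (a `binned_spectrum`), `fit`
#'   (`power_law_fit` or `NULL`), `null` (`null_ensemble` or `NULL`), and
#'   `stamp` (config hash and seeds).
#' @export
run_spectrum <- function(config) {
  cfg <- load_run_config(config)
  t0 <- as.numeric(Sys.time())
  n_req <- if (cfg$mode == "within" || cfg$estimator %in% c("pca", "cvpca")) 2L else 4L
  ins <- resolve_inputs(cfg, n_req)
  stage_msg("inputs", sprintf("%d response sets, %d x %d", length(ins),
                              nrow(ins[[1]]$values), ncol(ins[[1]]$values)), t0 = t0)
  folds <- make_folds(ins[[1]]$stimulus_ids, cfg$n_folds, cfg$seed_folds)
  spec <- switch(cfg$estimator,
    pca = {
      s <- pca_spectrum(ins[[1]])
      new_fold_spectrum(s$rank, s$value, fold = 1L)
    },
    cvpca = cvpca_spectrum(ins[[1]], ins[[2]]),
    crossdecomp = switch(cfg$mode,
      within = within_system_spectrum(ins[[1]], ins[[2]], folds),
      between = between_system_spectrum(ins[[1]], ins[[2]], ins[[3]], ins[[4]], folds),
      anatomical = anatomical_spectrum(ins[[1]], ins[[2]], ins[[3]], ins[[4]], folds),
      abort(sprintf("unknown mode `%s`", cfg$mode))),
    abort(sprintf("unknown estimator `%s`", cfg$estimator)))
  if (cfg$estimator != "crossdecomp" && isTRUE(cfg$normalize)) {
    spec <- normalize_by_channels(spec, ncol(ins[[1]]$values), ncol(ins[[2]]$values))
  }
  k_max <- cfg$bin_k_max %||% max(spec$rank)
  scheme <- make_log_bins(cfg$bin_k_min, k_max, cfg$bin_per_decade)
  bs <- aggregate_folds(bin_spectrum(spec, scheme))
  stage_msg("spectrum", sprintf("%d ranks -> %d bins", max(spec$rank), nrow(bs)), t0 = t0)

  null <- NULL
  if (cfg$n_perms > 0L && cfg$estimator == "crossdecomp") {
    null <- build_null_ensemble(ins[[1]], ins[[2]], folds, scheme,
                                n_perms = cfg$n_perms, seed = cfg$seed_perms,
                                y1 = if (n_req == 4L) ins[[3]] else NULL,
                                y2 = if (n_req == 4L) ins[[4]] else NULL,
                                mode = cfg$mode)
    bs <- flag_significance(bs, null, cfg$alpha)
    stage_msg("null", sprintf("%d permutations", cfg$n_perms), t0 = t0)
  }
  fit <- tryCatch(fit_power_law(bs, cfg$fit_range %||% c(1, Inf)),
                  error = function(e) NULL)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- config_stamp(cfg)
    out <- dplyr::mutate(as_tibble(bs), config_hash = stamp$config_hash,
                         seed_folds = stamp$seed_folds)
    readr::write_csv(out, file.path(cfg$output_dir, "spectrum.csv"), progress = FALSE)
    if (!is.null(null)) {
      nb <- dplyr::mutate(null$bins, config_hash = stamp$config_hash,
                          seed_perms = stamp$seed_perms)
      readr::write_csv(nb, file.path(cfg$output_dir, "null_percentiles.csv"),
                       progress = FALSE)
    }
    if (!is.null(fit)) {
      readr::write_csv(dplyr::mutate(glance(fit), config_hash = stamp$config_hash),
                       file.path(cfg$output_dir, "power_law.csv"), progress = FALSE)
    }
    write_run_log(cfg, stamp, file.path(cfg$output_dir, "run_log.json"))
    stage_msg("outputs", cfg$output_dir, t0 = t0)
  }
  list(spectrum = bs, fit = fit, null = null, stamp = config_stamp(cfg))
}

#' Run a configured spectral-correlation analysis
#'
#' Computes the between-subject spectrum and both within-subject spectra
#' with one shared fold plan, bins them on a common wide scheme, and
#' returns the spectral correlation table; optionally writes
#' `correlation.csv` and `run_log.json`.
#'
#' @inheritParams run_spectrum
#' @return A list with `correlation` (a `spectral_correlation` tibble) and
#'   `stamp`.
#' @export
run_correlation <- function(config) {
  cfg <- load_run_config(config)
  ins <- resolve_inputs(cfg, 4L)
  folds <- make_folds(ins[[1]]$stimulus_ids, cfg$n_folds, cfg$seed_folds)
  k_max <- cfg$bin_k_max %||%
    min(ncol(ins[[1]]$values), ncol(ins[[3]]$values), nrow(ins[[1]]$values))
  wide <- make_log_bins(cfg$bin_k_min, k_max, cfg$wide_per_decade)
  between <- bin_spectrum(
    between_system_spectrum(ins[[1]], ins[[2]], ins[[3]], ins[[4]], folds), wide)
  within_a <- bin_spectrum(within_system_spectrum(ins[[1]], ins[[2]], folds), wide)
  within_b <- bin_spectrum(within_system_spectrum(ins[[3]], ins[[4]], folds), wide)
  rk <- spectral_correlation(between, within_a, within_b)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- config_stamp(cfg)
    readr::write_csv(dplyr::mutate(as_tibble(rk), config_hash = stamp$config_hash,
                                   seed_folds = stamp$seed_folds),
                     file.path(cfg$output_dir, "correlation.csv"), progress = FALSE)
    write_run_log(cfg, stamp, file.path(cfg$output_dir, "run_log.json"))
  }
  list(correlation = rk, stamp = config_stamp(cfg))
}

#' Run a configured RSA control analysis
#'
#' Computes the RSA correlation between two subjects on the full data
#' ("high-D vs high-D") and with one side reduced to its leading principal
#' components ("high-D vs low-D"), with bootstrap error bars, for Pearson
#' and Spearman correlations; optionally writes `rsa.csv` and
#' `run_log.json`.
#'
#' @inheritParams run_spectrum
#' @return A list with `rsa` (tibble: `comparison`, `method`, `r`,
#'   `boot_mean`, `boot_sd`) and `stamp`.
#' @export
run_rsa <- function(config) {
  cfg <- load_run_config(config)
  ins <- resolve_inputs(cfg, 2L)
  a <- ins[[1]]; b <- ins[[2]]
  b_low <- low_rank_reconstruct(b, cfg$rsa_components)
  rows <- list()
  for (method in c("pearson", "spearman")) {
    for (cmp in c("high_high", "high_low")) {
      bb <- if (cmp == "high_high") b else b_low
      boot <- bootstrap_rsa(a, bb, n_boot = cfg$n_boot, fraction = cfg$rsa_fraction,
                            seed = cfg$seed_perms, method = method)
      rows[[length(rows) + 1L]] <- tibble(
        comparison = cmp, method = method,
        r = attr(boot, "point_estimate"),
        boot_mean = attr(boot, "mean"), boot_sd = attr(boot, "sd"))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- config_stamp(cfg)
    readr::write_csv(dplyr::mutate(out, config_hash = stamp$config_hash,
                                   seed_perms = stamp$seed_perms),
                     file.path(cfg$output_dir, "rsa.csv"), progress = FALSE)
    write_run_log(cfg, stamp, file.path(cfg$output_dir, "run_log.json"))
  }
  list(rsa = out, stamp = config_stamp(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
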