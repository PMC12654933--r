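#' Stimulus-by-channel response container
#'
#' A `response_set` holds one trial's responses: an `n` stimuli × `d`
#' channels numeric matrix together with stimulus and channel identifiers
#' and minimal provenance (subject, region, trial index). Channel values are
#' response amplitudes — typically z-units after [zscore_channels()].
#'
#' @param values Numeric matrix, `n` stimuli × `d` channels. No missing
#'   entries; `n >= 2`, `d >= 1`.
#' @param stimulus_ids Character vector of unique stimulus identifiers
#'   (length `n`). Defaults to `rownames(values)`.
#' @param channel_ids Character vector of unique channel identifiers
#'   (length `d`). Defaults to `colnames(values)`.
#' @param subject_id,region_id Labels for provenance.
#' @param trial_index Positive integer trial (repeat) index.
#'
#' @return An object of class `response_set`.
#' @examples
#' rs <- response_set(matrix(rnorm(12), 4, 3))
#' rs
#' @export
response_set <- function(values, stimulus_ids = rownames(values),
                         channel_ids = colnames(values),
                         subject_id = "subject1", region_id = "all",
                         trial_index = 1L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  n <- nrow(values); d <- ncol(values)
  if (n < 2L) abort("a response_set needs at least 2 stimuli (rows)")
  if (d < 1L) abort("a response_set needs at least 1 channel (column)")
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` contains missing or non-finite entries")
  }
  if (is.null(stimulus_ids)) stimulus_ids <- sprintf("s%04d", seq_len(n))
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%04d", seq_len(d))
  stimulus_ids <- as.character(stimulus_ids)
  channel_ids <- as.character(channel_ids)
  if (length(stimulus_ids) != n) abort("`stimulus_ids` length must equal nrow(values)")
  if (length(channel_ids) != d) abort("`channel_ids` length must equal ncol(values)")
  if (anyDuplicated(stimulus_ids)) abort("duplicate stimulus identifiers")
  if (anyDuplicated(channel_ids)) abort("duplicate channel identifiers")
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L) abort("`trial_index` must be a positive integer")
  dimnames(values) <- list(stimulus_ids, channel_ids)
  structure(
    list(values = values, stimulus_ids = stimulus_ids, channel_ids = channel_ids,
         subject_id = as.character(subject_id), region_id = as.character(region_id),
         trial_index = trial_index),
    class = "response_set"
  )
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set> %s / %s / trial %d: %d stimuli x %d channels\n",
              x$subject_id, x$region_id, x$trial_index,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.response_set <- function(x) dim(x$values)

#' Read / write a response set as delimited text
#'
#' The container is a delimited-text table — header row of channel ids,
#' first column `stimulus_id` — preceded by commented metadata lines of the
#' form `#key: value` for `subject_id`, `region_id` and `trial_index`.
#' Loading validates the object (unique identifiers, no missing entries) and
#' preserves the identifier order of the file.
#'
#' @param path File path. `format = "auto"` infers comma vs tab from the
#'   extension (`.tsv`/`.tab` → tab, otherwise comma).
#' @param format One of `"auto"`, `"csv"`, `"tsv"`.
#' @return `read_response_set()` returns a [response_set()];
#'   `write_response_set()` invisibly returns `path`.
#' @export
read_response_set <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  delim <- if (format == "tsv") "\t" else ","
  meta <- list(subject_id = "subject1", region_id = "all", trial_index = 1L)
  con_lines <- readLines(path, n = 10L)
  for (ln in grep("^#", con_lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  tbl <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) abort(sprintf("malformed file %s: needs a stimulus_id column plus channels", path))
  if (names(tbl)[1] != "stimulus_id") {
    abort(sprintf("malformed file %s: first column must be `stimulus_id`, found `%s`",
                  path, names(tbl)[1]))
  }
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort(sprintf("malformed file %s: non-numeric entries in `values`", path))
  if (anyNA(vals)) abort(sprintf("malformed file %s: missing entries in `values`", path))
  response_set(vals, stimulus_ids = tbl$stimulus_id, channel_ids = colnames(vals),
               subject_id = meta$subject_id, region_id = meta$region_id,
               trial_index = as.integer(meta$trial_index))
}

#' @param rs A [response_set()].
#' @rdname read_response_set
#' @export
write_response_set <- function(rs, path, format = c("auto", "csv", "tsv")) {
  stopifnot(inherits(rs, "response_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  delim <- if (format == "tsv") "\t" else ","
  header <- c(sprintf("#subject_id: %s", rs$subject_id),
              sprintf("#region_id: %s", rs$region_id),
              sprintf("#trial_index: %d", rs$trial_index))
  tbl <- tibble(stimulus_id = rs$stimulus_ids)
  tbl <- dplyr::bind_cols(tbl, as_tibble(rs$values, .name_repair = "minimal"))
  writeLines(header, path)
  readr::write_delim(tbl, path, delim = delim, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  invisible(path)
}

#' Restrict two response sets to their common stimuli
#'
#' Both sides are restricted to the intersection of their stimulus
#' identifiers and the rows are permuted into one canonical order
#' (lexicographic by stimulus id, C collation), so that row `i` of either
#' side is the same stimulus. This mirrors the standard step of analysing
#' only stimuli seen by every subject.
#'
#' @param a,b [response_set()] objects.
#' @return A list of class `paired_responses` with elements `side_a` and
#'   `side_b` (both `response_set`s over the identical ordered stimulus
#'   list) and `stimulus_ids`.
#' @export
align_common_stimuli <- function(a, b) {
  stopifnot(inherits(a, "response_set"), inherits(b, "response_set"))
  common <- intersect(a$stimulus_ids, b$stimulus_ids)
  if (length(common) < 2L) {
    abort(sprintf("insufficient overlap: only %d common stimuli (need >= 2)", length(common)))
  }
  common <- sort_c(common)
  take <- function(rs) {
    response_set(rs$values[match(common, rs$stimulus_ids), , drop = FALSE],
                 stimulus_ids = common, channel_ids = rs$channel_ids,
                 subject_id = rs$subject_id, region_id = rs$region_id,
                 trial_index = rs$trial_index)
  }
  structure(list(side_a = take(a), side_b = take(b), stimulus_ids = common),
            class = "paired_responses")
}

#' Assign stimuli to cross-validation folds
#'
#' Stimuli are shuffled with a seeded generator and dealt round-robin into
#' `n_folds` folds, so fold sizes differ by at most one and remainder
#' stimuli land in the lowest-index folds. With the default 8 folds each
#' rotation of the cross-validation trains on 7/8 of the stimuli and tests
#' on the held-out 1/8.
#'
#' @param stimulus_ids Character vector of stimulus identifiers.
#' @param n_folds Number of folds (default 8).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble of class `fold_plan` with columns `stimulus_id` and
#'   `fold`, plus attributes `n_folds` and `seed`.
#' @examples
#' fp <- make_folds(sprintf("s%03d", 1:16), n_folds = 8, seed = 1)
#' table(fp$fold)
#' @export
make_folds <- function(stimulus_ids, n_folds = 8L, seed = 1L) {
  stimulus_ids <- as.character(stimulus_ids)
  n <- length(stimulus_ids)
  n_folds <- as.integer(n_folds)
  if (anyDuplicated(stimulus_ids)) abort("duplicate stimulus identifiers")
  if (n_folds < 2L) abort("`n_folds` must be at least 2")
  if (n < n_folds) abort(sprintf("cannot split %d stimuli into %d folds", n, n_folds))
  shuffled <- withr::with_seed(as.integer(seed), sample(stimulus_ids))
  plan <- tibble(stimulus_id = shuffled, fold = rep(seq_len(n_folds), length.out = n))
  plan <- dplyr::arrange(plan, .data$stimulus_id)
  structure(plan, class = c("fold_plan", class(tibble())),
            n_folds = n_folds, seed = as.integer(seed))
}

#' @rdname make_folds
#' @param fp A `fold_plan`.
#' @param path Output CSV path.
#' @export
write_fold_plan <- function(fp, path) {
  stopifnot(inherits(fp, "fold_plan"))
  readr::write_csv(as_tibble(fp), path, progress = FALSE)
  invisible(path)
}

#' Z-score channels against a reference row subset
#'
#' Each channel is shifted and scaled by its mean and *population*
#' (divide-by-m) standard deviation computed over the reference rows only,
#' and the transform is applied to all rows. With the population convention
#' and reference = all rows, the trace of the channel covariance equals the
#' number of channels exactly, which is what makes the normalized training
#' spectrum of a self cross-decomposition sum to one.
#'
#' @param rs A [response_set()].
#' @param reference_rows Stimulus ids (character) or row indices (numeric)
#'   defining the reference subset; `NULL` (default) uses all rows.
#' @return A [response_set()] with transformed values.
#' @export
zscore_channels <- function(rs, reference_rows = NULL) {
  stopifnot(inherits(rs, "response_set"))
  v <- rs$values
  idx <- if (is.null(reference_rows)) {
    seq_len(nrow(v))
  } else if (is.character(reference_rows)) {
    i <- match(reference_rows, rs$stimulus_ids)
    if (anyNA(i)) abort("unknown stimulus ids in `reference_rows`")
    i
  } else {
    as.integer(reference_rows)
  }
  if (length(idx) < 1L) abort("`reference_rows` must be nonempty")
  ref <- v[idx, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- col_sd_pop(ref)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    abort(sprintf("zero spread over reference rows for channel(s): %s",
                  paste(rs$channel_ids[bad], collapse = ", ")))
  }
  out <- sweep(sweep(v, 2L, mu, `-`), 2L, sdv, `/`)
  response_set(out, stimulus_ids = rs$stimulus_ids, channel_ids = rs$channel_ids,
               subject_id = rs$subject_id, region_id = rs$region_id,
               trial_index = rs$trial_index)
}
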