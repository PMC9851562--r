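#' Write and read the two-file CSV trial format
#'
#' The on-disk format is a pair of plain CSVs: a metadata table with one row
#' per trial (`participant_id`, `trial_index`, `condition`, `word`, `ink`,
#' `correct_box`, `chosen_box`, `status`, `rt_ms`, `it_ms`) and a samples
#' table with one row per cursor sample (`participant_id`, `trial_index`,
#' `time_ms`, `x_px`, `y_px`), in screen-pixel coordinates with y increasing
#' downward. `write_trials()` emits exactly what `read_trials()` accepts, so
#' the pair round-trips.
#'
#' @param data A `stroop_data` object or a list with `trials` and `samples`
#'   tibbles.
#' @param metadata_path,samples_path Paths of the two CSV files.
#' @return `write_trials()` invisibly returns the two paths; `read_trials()`
#'   returns a list with `trials` and `samples` tibbles.
#' @export
write_trials <- function(data, metadata_path, samples_path) {
  meta_cols <- c("participant_id", "trial_index", "condition", "word", "ink",
                 "correct_box", "chosen_box", "status", "rt_ms", "it_ms")
  trials <- dplyr::select(data$trials, dplyr::any_of(c(meta_cols, "pe_regime", "pull_w0")))
  readr::write_csv(trials, metadata_path)
  readr::write_csv(data$samples, samples_path)
  invisible(c(metadata_path, samples_path))
}

#' @rdname write_trials
#' @export
read_trials <- function(metadata_path, samples_path) {
  for (p in c(metadata_path, samples_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  trials <- readr::read_csv(metadata_path, show_col_types = FALSE,
                            progress = FALSE)
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  need_meta <- c("participant_id", "trial_index", "condition", "correct_box",
                 "chosen_box", "status", "rt_ms", "it_ms")
  need_samp <- c("participant_id", "trial_index", "time_ms", "x_px", "y_px")
  miss <- setdiff(need_meta, names(trials))
  if (length(miss) > 0) {
    abort(paste0("Metadata file is missing column(s): ", paste(miss, collapse = ", ")),
          class = "strooptrace_format_error")
  }
  miss <- setdiff(need_samp, names(samples))
  if (length(miss) > 0) {
    abort(paste0("Samples file is missing column(s): ", paste(miss, collapse = ", ")),
          class = "strooptrace_format_error")
  }
  key <- function(d) paste(d$participant_id, d$trial_index)
  orphan <- setdiff(unique(key(samples)), key(trials))
  if (length(orphan) > 0) {
    abort(paste0("Samples reference unknown trial id(s): ",
                 paste(head(orphan, 5), collapse = "; "),
                 if (length(orphan) > 5) " ..."),
          class = "strooptrace_format_error")
  }
  # times must be nondecreasing in file order within each trial
  nonmono <- samples |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::summarise(bad = any(diff(.data$time_ms) < 0), .groups = "drop") |>
    dplyr::filter(.data$bad)
  if (nrow(nonmono) > 0) {
    abort(paste0("Non-monotone sample times within trial(s): ",
                 paste(head(key(nonmono), 5), collapse = "; ")),
          class = "strooptrace_data_error")
  }
  list(trials = trials, samples = samples)
}
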