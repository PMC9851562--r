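#' Apply the standard trial exclusion rules
#'
#' Removes, in order: trials with no response (timeouts/omissions), trials
#' with an incorrect response, and then - among the remaining correct trials -
#' trials whose response time falls more than 3 SDs above or below the mean
#' latency of their own participant x condition cell (mean and SD computed on
#' those remaining correct trials). Cells with fewer than two trials, or with
#' zero RT spread, contribute no outlier removals. This cell-wise rule trims
#' extreme latencies without disproportionately affecting any one condition
#' or participant.
#'
#' @param trials Trial metadata tibble (needs `participant_id`, `condition`,
#'   `status`, `rt_ms`).
#' @param sd_limit Outlier cut in cell SD units (default 3).
#' @return The kept trials, with an `ExclusionReport` available via
#'   [exclusion_report()].
#' @export
#' @examples
#' dat <- simulate_trials(sim_config(n_participants = 2, seed = 1),
#'                        include_samples = FALSE)
#' kept <- filter_trials(dat$trials)
#' exclusion_report(kept)
filter_trials <- function(trials, sd_limit = 3) {
  n_total <- nrow(trials)
  omitted <- dplyr::filter(trials, .data$status == "timeout")
  errored <- dplyr::filter(trials, .data$status == "error")
  correct <- dplyr::filter(trials, .data$status == "correct")

  flagged <- correct |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::mutate(
      .cell_n = dplyr::n(),
      .cell_mean = mean(.data$rt_ms),
      .cell_sd = sd(.data$rt_ms),
      .outlier = .data$.cell_n >= 2 & !is.na(.data$.cell_sd) & .data$.cell_sd > 0 &
        abs(.data$rt_ms - .data$.cell_mean) > sd_limit * .data$.cell_sd
    ) |>
    dplyr::ungroup()
  kept <- flagged |>
    dplyr::filter(!.data$.outlier) |>
    dplyr::select(-dplyr::starts_with(".cell"), -".outlier")

  per_part <- function(d, rule) {
    if (nrow(d) == 0) {
      return(tibble::tibble(participant_id = character(), rule = character(),
                            n = integer()))
    }
    dplyr::count(d, .data$participant_id) |>
      dplyr::mutate(rule = rule) |>
      dplyr::select("participant_id", "rule", "n")
  }
  report <- structure(
    list(
      n_total = n_total,
      counts = tibble::tibble(
        rule = c("omission", "error", "rt_outlier"),
        n = c(nrow(omitted), nrow(errored), sum(flagged$.outlier)),
        pct = 100 * c(nrow(omitted), nrow(errored), sum(flagged$.outlier)) /
          max(n_total, 1)
      ),
      by_participant = dplyr::bind_rows(
        per_part(omitted, "omission"),
        per_part(errored, "error"),
        per_part(dplyr::filter(flagged, .data$.outlier), "rt_outlier")
      ),
      small_cells = flagged |>
        dplyr::filter(.data$.cell_n < 2) |>
        dplyr::distinct(.data$participant_id, .data$condition)
    ),
    class = "exclusion_report"
  )
  attr(kept, "exclusion_report") <- report
  kept
}

#' @rdname filter_trials
#' @param kept A tibble returned by [filter_trials()].
#' @export
exclusion_report <- function(kept) {
  rep <- attr(kept, "exclusion_report")
  if (is.null(rep)) abort("No exclusion report attached; run filter_trials() first")
  rep
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> ", x$n_total, " trials\n", sep = "")
  print(x$counts)
  if (nrow(x$small_cells) > 0) {
    cat("  (", nrow(x$small_cells),
        " cells with < 2 trials: outlier rule not applied)\n", sep = "")
  }
  invisible(x)
}

#' Remap trajectories rightward and align their endpoints
#'
#' For each trial whose correct response box lies left of the start box, the
#' x coordinates are mirrored about the start-box centre, so all movements
#' run toward the right-hand side and leftward excursions always mean
#' "toward the incorrect response". Each trajectory is then mapped by a
#' translation plus independent x and y scalings so its first sample lands
#' exactly at (0, 0) and its last sample at (1, 1.5); y increases toward the
#' response boxes after alignment regardless of the screen's pixel-y
#' direction.
#'
#' @param samples Long samples tibble (`participant_id`, `trial_index`,
#'   `time_ms`, `x_px`, `y_px`).
#' @param trials Trial metadata restricted to the trials to align (typically
#'   the output of [filter_trials()]); needs `correct_box`.
#' @param layout A [screen_layout()].
#' @return Long tibble `participant_id`, `trial_index`, `time_ms`, `x`, `y`,
#'   `remapped` in aligned units.
#' @export
remap_and_align <- function(samples, trials, layout) {
  validate_screen_layout(layout)
  box_x <- vapply(layout$response_centers, `[`, numeric(1), 1)
  start_x <- layout$start_center[1]
  meta <- trials |>
    dplyr::transmute(
      .data$participant_id, .data$trial_index,
      remapped = unname(box_x[.data$correct_box] < start_x)
    )
  out <- samples |>
    dplyr::inner_join(meta, by = c("participant_id", "trial_index")) |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::arrange(.data$time_ms, .by_group = TRUE) |>
    dplyr::mutate(
      xr = ifelse(.data$remapped, 2 * start_x - .data$x_px, .data$x_px),
      x = align_axis(.data$xr, 1),
      y = align_axis(.data$y_px, 1.5)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "trial_index", "time_ms", "x", "y",
                  "remapped")
  out
}

# affine map of one coordinate: first value -> 0, last value -> target
align_axis <- function(v, target) {
  span <- v[length(v)] - v[1]
  if (length(v) < 2 || span == 0) {
    abort("Degenerate path: first and last samples coincide on an axis",
          class = "strooptrace_alignment_error")
  }
  (v - v[1]) / span * target
}

#' Time-normalize an aligned trajectory to 101 steps
#'
#' Linearly interpolates x(t) and y(t) at `n_steps` equally spaced times
#' spanning the full trial duration from the start-box click to response,
#' including the pre-initiation dwell. Step `s` therefore corresponds to
#' approximately `(s - 1)%` of the total response duration.
#'
#' @param aligned Output of [remap_and_align()].
#' @param n_steps Number of time steps (default 101).
#' @return Tibble `participant_id`, `trial_index`, `step` (1..n_steps), `x`,
#'   `y`, `total_duration_ms`.
#' @export
time_normalize <- function(aligned, n_steps = 101) {
  aligned |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::arrange(.data$time_ms, .by_group = TRUE) |>
    dplyr::reframe(time_normalize_one(.data$time_ms, .data$x, .data$y, n_steps))
}

time_normalize_one <- function(time_ms, x, y, n_steps) {
  dur <- time_ms[length(time_ms)] - time_ms[1]
  if (length(time_ms) < 2 || dur <= 0) {
    abort("Cannot time-normalize a trial of zero duration",
          class = "strooptrace_normalize_error")
  }
  grid <- seq(time_ms[1], time_ms[length(time_ms)], length.out = n_steps)
  tibble::tibble(
    step = seq_len(n_steps),
    x = approx(time_ms, x, xout = grid, ties = "ordered")$y,
    y = approx(time_ms, y, xout = grid, ties = "ordered")$y,
    total_duration_ms = dur
  )
}

#' Space-normalize an aligned trajectory to 100 points
#'
#' Resamples each trajectory at `n_points` positions evenly spaced along its
#' arc length (polyline length), preserving the endpoints. Dwell samples
#' (repeated points) contribute zero arc length and do not affect the result.
#'
#' @param aligned Output of [remap_and_align()].
#' @param n_points Number of output points (default 100).
#' @return Tibble `participant_id`, `trial_index`, `point` (1..n_points),
#'   `x`, `y`.
#' @export
space_normalize <- function(aligned, n_points = 100) {
  aligned |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::arrange(.data$time_ms, .by_group = TRUE) |>
    dplyr::reframe(space_normalize_one(.data$x, .data$y, n_points))
}

space_normalize_one <- function(x, y, n_points) {
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    abort("Cannot space-normalize a path of zero arc length",
          class = "strooptrace_normalize_error")
  }
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  grid <- seq(0, arc[length(arc)], length.out = n_points)
  tibble::tibble(
    point = seq_len(n_points),
    x = approx(arc, x, xout = grid, ties = "ordered")$y,
    y = approx(arc, y, xout = grid, ties = "ordered")$y
  )
}
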