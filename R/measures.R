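#' Signed orthogonal deviation from the direct path
#'
#' Distance from a point to the straight line joining the aligned start
#' (0, 0) and end (1, 1.5) points, signed so that positive values lie above
#' the direct path - i.e. to the left of the start-to-end direction, which
#' after rightward remapping is the incorrect-response side. Computed as the
#' 2-D cross product of the path direction with the point, divided by the
#' path length.
#'
#' @param x,y Point coordinates in aligned units (vectorized).
#' @param start,end Numeric length-2 anchors of the direct path.
#' @return Signed deviation(s) in normalized units.
#' @export
#' @examples
#' signed_deviation(0, 1)   # above the direct path: positive
#' signed_deviation(1, 0)   # below: negative
signed_deviation <- function(x, y, start = c(0, 0), end = c(1, 1.5)) {
  p <- end - start
  qx <- x - start[1]
  qy <- y - start[2]
  (p[1] * qy - p[2] * qx) / sqrt(sum(p^2))
}

#' Maximum deviation above the direct path
#'
#' The maximum of the signed orthogonal deviation over all samples of an
#' aligned trajectory. A path that never rises above the direct line yields a
#' value less than or equal to zero (the sign is preserved rather than
#' floored at zero, so a consistently below-path trajectory is
#' distinguishable from a straight one).
#'
#' @param x,y Coordinates of one aligned trajectory.
#' @inheritParams signed_deviation
#' @return Single numeric, normalized units.
#' @export
max_deviation_above <- function(x, y, start = c(0, 0), end = c(1, 1.5)) {
  max(signed_deviation(x, y, start, end))
}

#' Initiation time of one trial
#'
#' Time from the start-box click (first sample) to the first sample whose
#' cumulative displacement from the start position exceeds
#' `movement_threshold` pixels. The default threshold of 0 treats any
#' positional change as movement. If the cursor never moves, the trial
#' duration is returned with attribute `no_movement = TRUE`.
#'
#' @param time_ms,x,y Sample times and positions of one trial (raw or aligned
#'   coordinates; only displacement from the first sample is used).
#' @param movement_threshold Displacement threshold in the input units.
#' @return Initiation time in ms.
#' @export
initiation_time <- function(time_ms, x, y, movement_threshold = 0) {
  disp <- sqrt((x - x[1])^2 + (y - y[1])^2)
  idx <- which(disp > movement_threshold)
  if (length(idx) == 0) {
    out <- time_ms[length(time_ms)] - time_ms[1]
    attr(out, "no_movement") <- TRUE
    return(out)
  }
  time_ms[idx[1]] - time_ms[1]
}

#' Response time of one trial
#'
#' Time from the start-box click to response-box selection, i.e. the last
#' sample time minus the first. Invariant under remapping and alignment,
#' which leave sample times untouched.
#'
#' @param time_ms Sample times of one trial.
#' @return Response time in ms.
#' @export
response_time <- function(time_ms) {
  time_ms[length(time_ms)] - time_ms[1]
}

#' Trial-level kinematic measures
#'
#' Computes, for every aligned trial, the initiation time (from the raw
#' samples, so dwell at the start box is measured before any alignment
#' rescaling), the response time, and the maximum deviation above the direct
#' path evaluated on the full-resolution aligned trajectory.
#'
#' @param aligned Output of [remap_and_align()].
#' @param trials Trial metadata; `condition` is joined onto the result when
#'   present.
#' @param movement_threshold Displacement threshold passed to
#'   [initiation_time()], in aligned units.
#' @return Tibble with one row per trial: `participant_id`, `trial_index`,
#'   `condition` (if available), `it_ms`, `rt_ms`, `md_above`.
#' @export
trial_measures <- function(aligned, trials = NULL, movement_threshold = 0) {
  out <- aligned |>
    dplyr::group_by(.data$participant_id, .data$trial_index) |>
    dplyr::arrange(.data$time_ms, .by_group = TRUE) |>
    dplyr::summarise(
      it_ms = as.numeric(initiation_time(.data$time_ms, .data$x, .data$y,
                                         movement_threshold)),
      rt_ms = response_time(.data$time_ms),
      md_above = max_deviation_above(.data$x, .data$y),
      .groups = "drop"
    )
  if (!is.null(trials) && "condition" %in% names(trials)) {
    out <- dplyr::left_join(
      out, dplyr::select(trials, "participant_id", "trial_index", "condition"),
      by = c("participant_id", "trial_index")
    )
  }
  out
}

#' 101-step deviation and x-coordinate profiles
#'
#' Evaluates, at each of the 101 normalized time steps, the signed orthogonal
#' deviation from the direct path (`deviation`) and the x coordinate
#' (`x_coordinate`). Positive deviations and negative x both indicate the
#' incorrect-response side; the endpoints satisfy `deviation = 0` at steps 1
#' and 101, `x = 0` at step 1 and `x = 1` at step 101.
#'
#' @param tnorm Output of [time_normalize()].
#' @param trials Trial metadata; `condition` is joined on when present.
#' @return Long tibble: `participant_id`, `trial_index`, `condition` (if
#'   available), `step`, `deviation`, `x_coordinate`.
#' @export
trajectory_profiles <- function(tnorm, trials = NULL) {
  out <- tnorm |>
    dplyr::mutate(
      deviation = signed_deviation(.data$x, .data$y),
      x_coordinate = .data$x
    ) |>
    dplyr::select("participant_id", "trial_index", "step", "deviation",
                  "x_coordinate")
  if (!is.null(trials) && "condition" %in% names(trials)) {
    out <- dplyr::left_join(
      out, dplyr::select(trials, "participant_id", "trial_index", "condition"),
      by = c("participant_id", "trial_index")
    )
  }
  out
}
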