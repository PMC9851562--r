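#' Component time courses across the 101 normalized time steps
#'
#' Fits, at every time step, a mixed model of the step's measure value on the
#' six conditions (colour-neutral reference) with a by-participant random
#' intercept - a simplified per-step structure chosen so that 101 fits stay
#' fast and stable; setting `per_step_slope = TRUE` additionally retains, per
#' step, the single by-participant slope of the standard-incongruent
#' condition when a likelihood-ratio test supports it. All eight component
#' contrasts are then evaluated per step with `ci_level` confidence
#' intervals. Steps whose fit fails are flagged (`converged = FALSE`) and
#' treated as non-significant when locating runs. Sustained effects are
#' summarized as maximal runs of at least `min_run` consecutive steps whose
#' CI excludes zero, and the per-component peak is the largest estimate in
#' the measure's expected direction (positive deviations, negative x), ties
#' going to the earliest step.
#'
#' @param profiles Output of [trajectory_profiles()] (needs `condition`; join
#'   the trial metadata first or pass `trials`).
#' @param measure `"deviation"` or `"x_coordinate"`.
#' @param trials Optional trial metadata supplying `condition` when the
#'   profiles lack it.
#' @param ci_level Per-step confidence level (default 0.95).
#' @param min_run Minimum run length for a reported interval (default 10; 5
#'   is conventional for display).
#' @param per_step_slope Retain a standard-incongruent by-participant slope
#'   per step when supported (slower; default `FALSE`).
#' @return A `stroop_timecourse` object: `steps` (tibble: `measure`,
#'   `component`, `step`, `estimate`, `se`, `df`, `ci_low`, `ci_high`,
#'   `converged`, `significant`), `intervals` (tibble: `measure`,
#'   `component`, `start_step`, `end_step`), `peaks` (tibble: `measure`,
#'   `component`, `peak_step`, `peak_estimate`), `measure`, `ci_level`,
#'   `min_run`.
#' @export
fit_timecourse <- function(profiles, measure = c("deviation", "x_coordinate"),
                           trials = NULL, ci_level = 0.95, min_run = 10,
                           per_step_slope = FALSE) {
  measure <- match.arg(measure)
  if (!"condition" %in% names(profiles)) {
    if (is.null(trials)) {
      abort("`profiles` lacks a condition column; supply `trials`")
    }
    profiles <- dplyr::left_join(
      profiles,
      dplyr::select(trials, "participant_id", "trial_index", "condition"),
      by = c("participant_id", "trial_index")
    )
  }
  steps <- sort(unique(profiles$step))
  by_step <- split(profiles, profiles$step)
  res <- purrr::map_dfr(as.character(steps), function(s) {
    d <- by_step[[s]]
    comp <- step_components(d, measure, ci_level, per_step_slope)
    dplyr::mutate(comp, step = as.integer(s), .before = 1)
  })
  res <- dplyr::mutate(
    res,
    measure = measure,
    significant = .data$converged & (.data$ci_low > 0 | .data$ci_high < 0)
  ) |>
    dplyr::select("measure", "component", "step", "estimate", "se", "df",
                  "ci_low", "ci_high", "converged", "significant") |>
    dplyr::arrange(.data$component, .data$step)

  direction <- if (measure == "deviation") 1 else -1
  peaks <- res |>
    dplyr::group_by(.data$measure, .data$component) |>
    dplyr::summarise(
      peak_step = peak_step(.data$step, .data$estimate, direction),
      peak_estimate = .data$estimate[match(.data$peak_step, .data$step)],
      .groups = "drop"
    )
  intervals <- res |>
    dplyr::group_by(.data$measure, .data$component) |>
    dplyr::reframe(significant_intervals(.data$significant, min_run = min_run,
                                         steps = .data$step))
  structure(
    list(steps = res, intervals = intervals, peaks = peaks, measure = measure,
         ci_level = ci_level, min_run = min_run),
    class = "stroop_timecourse"
  )
}

# one per-step model: all eight contrasts, with graceful failure
step_components <- function(d, measure, ci_level, per_step_slope) {
  fail <- dplyr::mutate(component_table()[, "component"],
                        estimate = NA_real_, se = NA_real_, df = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        converged = FALSE)
  out <- tryCatch(suppressWarnings({
    structure <- "intercept"
    if (per_step_slope) {
      base <- fit_lmm(d, measure, "intercept")
      with_sl <- fit_lmm(d, measure, c("intercept", "standard_incongruent"))
      if (with_sl$converged && !with_sl$singular) {
        stat <- max(0, 2 * (as.numeric(logLik(with_sl$model)) -
                              as.numeric(logLik(base$model))))
        if (pchisq(stat, 1, lower.tail = FALSE) <= 0.20) {
          structure <- c("intercept", "standard_incongruent")
        }
      }
    }
    fit <- fit_lmm(d, measure, structure)
    cc <- component_contrasts(fit, ci_level = ci_level)
    dplyr::tibble(component = cc$component, estimate = cc$estimate,
                  se = cc$se, df = cc$df, ci_low = cc$ci_low,
                  ci_high = cc$ci_high,
                  converged = fit$converged & is.finite(cc$se))
  }), error = function(e) fail)
  out$converged[!is.finite(out$se) | !is.finite(out$df)] <- FALSE
  out
}

#' Maximal runs of sustained significance
#'
#' Scans a logical significance sequence (or per-step CI bounds) for maximal
#' runs of consecutive steps whose confidence interval excludes zero and
#' keeps runs of at least `min_run` steps. Runs found at a larger `min_run`
#' are always a subset of those at a smaller one.
#'
#' @param significant Logical vector, one element per step, or a data frame
#'   with `ci_low` and `ci_high` columns.
#' @param min_run Minimum run length (default 10).
#' @param steps Step labels (defaults to 1..length).
#' @return Tibble with `start_step`, `end_step`, `length`.
#' @export
#' @examples
#' significant_intervals(c(rep(FALSE, 45), rep(TRUE, 48), rep(FALSE, 8)))
significant_intervals <- function(significant, min_run = 10, steps = NULL) {
  if (is.data.frame(significant)) {
    significant <- significant$ci_low > 0 | significant$ci_high < 0
  }
  significant[is.na(significant)] <- FALSE
  if (is.null(steps)) steps <- seq_along(significant)
  r <- rle(significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  tibble::tibble(
    start_step = steps[starts[keep]],
    end_step = steps[ends[keep]],
    length = r$lengths[keep]
  )
}

# earliest step achieving the extremum in the expected direction
peak_step <- function(steps, estimate, direction) {
  v <- direction * estimate
  v[is.na(v)] <- -Inf
  steps[which.max(v)]
}

#' Peak of a component time course
#'
#' @param tc A `stroop_timecourse`.
#' @param component Component name (default `"total_stroop"`).
#' @return One-row tibble with `peak_step` and `peak_estimate`.
#' @export
timecourse_peak <- function(tc, component = "total_stroop") {
  stopifnot(inherits(tc, "stroop_timecourse"))
  dplyr::filter(tc$peaks, .data$component == !!component) |>
    dplyr::select("peak_step", "peak_estimate")
}

#' @export
print.stroop_timecourse <- function(x, ...) {
  cat("<stroop_timecourse> measure: ", x$measure, ", ",
      dplyr::n_distinct(x$steps$step), " steps, ", 100 * x$ci_level,
      "% CIs, min run ", x$min_run, "\n", sep = "")
  print(x$peaks)
  if (nrow(x$intervals) > 0) {
    cat("sustained intervals:\n")
    print(x$intervals)
  } else {
    cat("no sustained intervals\n")
  }
  invisible(x)
}
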