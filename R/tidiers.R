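#' Tidy a fitted condition mixed model
#'
#' Returns one row per fixed-effect term (the colour-neutral intercept and
#' the five condition offsets), with standard errors and Satterthwaite
#' degrees of freedom where available.
#'
#' @param x A `stroop_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `df`, `statistic`.
#' @method tidy stroop_fit
#' @export
tidy.stroop_fit <- function(x, ...) {
  if (inherits(x$model, "merMod")) {
    s <- as.data.frame(coef(summary(x$model)))
    tibble::tibble(
      term = rownames(s), estimate = s$Estimate, std.error = s$`Std. Error`,
      df = s$df, statistic = s$`t value`
    )
  } else {
    s <- as.data.frame(coef(summary(x$model)))
    tibble::tibble(
      term = rownames(s), estimate = s$Estimate, std.error = s$`Std. Error`,
      df = stats::df.residual(x$model), statistic = s$`t value`
    )
  }
}

#' One-row model summary of a condition mixed model
#'
#' @param x A `stroop_fit`.
#' @param ... Unused.
#' @return Tibble with measure, retained random structure, number of
#'   observations, REML criterion (NA for the OLS fallback), singularity and
#'   convergence flags.
#' @method glance stroop_fit
#' @export
glance.stroop_fit <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    structure = paste(x$structure, collapse = "+"),
    nobs = stats::nobs(x$model),
    reml_crit = if (inherits(x$model, "merMod")) lme4::REMLcrit(x$model) else NA_real_,
    singular = x$singular,
    converged = x$converged,
    df_method = x$df_method
  )
}

#' @method tidy stroop_components
#' @export
tidy.stroop_components <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method tidy stroop_timecourse
#' @export
tidy.stroop_timecourse <- function(x, ...) {
  x$steps
}

#' @method glance stroop_timecourse
#' @export
glance.stroop_timecourse <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, ci_level = x$ci_level, min_run = x$min_run,
    n_steps = dplyr::n_distinct(x$steps$step),
    n_intervals = nrow(x$intervals),
    n_failed_steps = sum(!x$steps$converged) / dplyr::n_distinct(x$steps$component)
  )
}

#' @method tidy stroop_clusters
#' @export
tidy.stroop_clusters <- function(x, ...) {
  dplyr::mutate(x$assignments,
                is_partial_error = .data$cluster %in% x$pe_clusters)
}

#' @method glance stroop_clusters
#' @export
glance.stroop_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k, linkage = x$linkage, distance = x$distance,
    n_trials = nrow(x$assignments),
    pe_clusters = paste(x$pe_clusters, collapse = ","),
    pe_fraction = mean(x$assignments$cluster %in% x$pe_clusters)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
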