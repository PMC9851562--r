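#' Select a parsimonious by-participant random-effect structure
#'
#' Starting from a by-participant random intercept plus uncorrelated random
#' slopes for all five non-reference conditions (dummy-coded against the
#' colour-neutral baseline), slopes are dropped one at a time - always the
#' slope with the smallest estimated variance - whenever the fit is singular
#' or fails to converge, or when a likelihood-ratio test does not support the
#' slope at `alpha`. The random intercept is always retained. With at most
#' one observation per participant x condition cell (as for partial-error
#' rates) only the intercept is estimable and it is returned directly. The
#' procedure is deterministic given the data.
#'
#' @param data Tibble with `participant_id`, `condition` and the measure
#'   column.
#' @param measure Name of the measure column.
#' @param alpha Retention threshold of the likelihood-ratio test
#'   (default 0.20).
#' @return Character vector of retained random terms: `"intercept"` plus the
#'   condition labels whose slopes were kept.
#' @export
select_random_structure <- function(data, measure, alpha = 0.20) {
  check_measure_data(data, measure)
  if (dplyr::n_distinct(data$participant_id) < 2) {
    return("intercept")
  }
  cell_max <- data |>
    dplyr::count(.data$participant_id, .data$condition) |>
    dplyr::pull(.data$n) |>
    max()
  if (cell_max < 2) {
    return("intercept")
  }
  slopes <- setdiff(stroop_conditions(), reference_condition())
  repeat {
    fit <- fit_lmm(data, measure, structure = c("intercept", slopes))
    if (length(slopes) == 0) break
    vars <- slope_variances(fit)
    weakest <- names(vars)[which.min(vars)]
    if (!fit$converged || fit$singular) {
      slopes <- setdiff(slopes, weakest)
      next
    }
    reduced <- fit_lmm(data, measure,
                       structure = c("intercept", setdiff(slopes, weakest)))
    stat <- max(0, 2 * (as.numeric(logLik(fit$model)) -
                          as.numeric(logLik(reduced$model))))
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (p > alpha) {
      slopes <- setdiff(slopes, weakest)
    } else {
      break
    }
  }
  c("intercept", slopes)
}

#' Fit the condition mixed model for one measure
#'
#' REML linear mixed model of the measure on the six stimulus-type
#' conditions, dummy-coded with colour-neutral as the reference level, with a
#' by-participant random intercept and any retained uncorrelated
#' by-participant condition slopes. With a single participant the model
#' degenerates to ordinary least-squares regression.
#'
#' @inheritParams select_random_structure
#' @param structure Random structure descriptor from
#'   [select_random_structure()]; `"intercept"` alone for intercept-only.
#' @param reference Dummy-coding reference level (default colour-neutral).
#'   Component contrasts are invariant to this choice; it only relabels the
#'   coefficients.
#' @return A `stroop_fit` object: the fitted model plus `measure`,
#'   `structure`, `reference`, `singular` and `converged` flags and the df
#'   method used.
#' @export
fit_lmm <- function(data, measure, structure = "intercept",
                    reference = reference_condition()) {
  check_measure_data(data, measure)
  data <- dplyr::mutate(
    data,
    condition = condition_factor(.data$condition, reference = reference),
    .value = .data[[measure]]
  )
  data <- dplyr::filter(data, !is.na(.data$.value))
  slopes <- setdiff(structure, "intercept")
  for (sl in slopes) {
    data[[paste0("d_", sl)]] <- as.numeric(data$condition == sl)
  }
  single_participant <- dplyr::n_distinct(data$participant_id) < 2
  if (single_participant) {
    model <- stats::lm(.value ~ condition, data = data)
    return(new_stroop_fit(model, measure, "none", reference,
                          singular = FALSE, converged = TRUE,
                          df_method = "residual"))
  }
  re <- c("(1 | participant_id)",
          sprintf("(0 + d_%s | participant_id)", slopes))
  form <- as.formula(paste(".value ~ condition +", paste(re, collapse = " + ")))
  model <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = data, REML = TRUE)
    )),
    error = function(e) NULL
  )
  if (is.null(model)) {
    # degenerate data (e.g. zero residual variance) breaks the mixed-model
    # machinery; ordinary least squares is exact there
    model <- stats::lm(.value ~ condition, data = data)
    return(new_stroop_fit(model, measure, "none", reference,
                          singular = FALSE, converged = TRUE,
                          df_method = "residual"))
  }
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  new_stroop_fit(model, measure, structure, reference,
                 singular = lme4::isSingular(model, tol = 1e-4),
                 converged = converged, df_method = "satterthwaite")
}

new_stroop_fit <- function(model, measure, structure, reference, singular,
                           converged, df_method) {
  structure(
    list(model = model, measure = measure, structure = structure,
         reference = reference, singular = singular, converged = converged,
         df_method = df_method),
    class = "stroop_fit"
  )
}

check_measure_data <- function(data, measure) {
  need <- c("participant_id", "condition", measure)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("Measure data is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
}

# by-participant slope variances, named by condition
slope_variances <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  sl <- vc[grepl("^d_", vc$var1) & !is.na(vc$var1), ]
  setNames(sl$vcov, sub("^d_", "", sl$var1))
}

# estimate a single fixed-effect contrast with SE, df and CI
fixed_contrast <- function(fit, L, ci_level) {
  if (inherits(fit$model, "lmerModLmerTest")) {
    res <- lmerTest::contest1D(fit$model, L)
    est <- res$Estimate
    se <- res$`Std. Error`
    df <- res$df
  } else {
    b <- coef(fit$model)
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% vcov(fit$model) %*% L))
    df <- stats::df.residual(fit$model)
  }
  half <- qt(1 - (1 - ci_level) / 2, df) * se
  tibble::tibble(estimate = est, se = se, df = df,
                 ci_low = est - half, ci_high = est + half)
}

# contrast vector over the fixed effects for a single condition's marginal
# mean (intercept + its dummy coefficient) or, with intercept_weight = 0, for
# a pure condition offset
condition_L <- function(fit, condition, intercept_weight = 1) {
  nm <- names(fixef_coefs(fit))
  L <- setNames(numeric(length(nm)), nm)
  L["(Intercept)"] <- intercept_weight
  ref <- fit$reference %||% reference_condition()
  if (condition != ref) {
    L[paste0("condition", condition)] <- 1
  }
  L
}

fixef_coefs <- function(fit) {
  if (inherits(fit$model, "merMod")) lme4::fixef(fit$model) else coef(fit$model)
}

#' Estimated marginal means per condition
#'
#' Model-implied mean of each stimulus-type condition: the intercept for the
#' colour-neutral reference, intercept plus the condition's dummy coefficient
#' otherwise, with standard errors from the fixed-effect covariance matrix
#' and Satterthwaite degrees of freedom (residual df for the single
#' participant OLS fallback).
#'
#' @param fit A `stroop_fit` from [fit_lmm()].
#' @param ci_level Confidence level of the reported interval (default 0.95).
#' @return Tibble: `condition`, `mean`, `se`, `df`, `ci_low`, `ci_high`,
#'   carrying the fit as attribute `fit`.
#' @export
marginal_means <- function(fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "stroop_fit"))
  out <- purrr::map_dfr(stroop_conditions(), function(cond) {
    res <- fixed_contrast(fit, condition_L(fit, cond), ci_level)
    dplyr::mutate(res, condition = cond, .before = 1)
  })
  out <- dplyr::rename(out, mean = "estimate")
  attr(out, "fit") <- fit
  out
}

#' The eight Stroop components with confidence intervals
#'
#' Evaluates every component of [component_table()] as a contrast of the
#' model's marginal means (equivalently, of its dummy coefficients: the
#' intercept cancels from every difference), with standard errors from the
#' fixed-effect covariance, Satterthwaite degrees of freedom, and two-sided
#' confidence intervals at `ci_level`. The additivity identities -
#' interference + facilitation = total, the three conflict components sum to
#' interference, the two facilitation components sum to facilitation - hold
#' exactly for every fit because the contrasts telescope.
#'
#' @param fit A `stroop_fit`, or the output of [marginal_means()].
#' @param ci_level Confidence level (0.99 for the global measures mirroring a
#'   Bonferroni correction over the five subcomponents; 0.95 is used per time
#'   step).
#' @return A `stroop_components` tibble: `component`, `minuend`,
#'   `subtrahend`, `estimate`, `se`, `df`, `ci_low`, `ci_high`, `ci_level`.
#' @export
component_contrasts <- function(fit, ci_level = 0.99) {
  if (!inherits(fit, "stroop_fit")) {
    fit <- attr(fit, "fit")
    if (is.null(fit)) {
      abort("`fit` must be a stroop_fit or the output of marginal_means()")
    }
  }
  tab <- component_table()
  out <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    L <- condition_L(fit, tab$minuend[i], intercept_weight = 0) -
      condition_L(fit, tab$subtrahend[i], intercept_weight = 0)
    res <- fixed_contrast(fit, L, ci_level)
    dplyr::mutate(res,
                  component = tab$component[i], minuend = tab$minuend[i],
                  subtrahend = tab$subtrahend[i], .before = 1)
  })
  out$ci_level <- ci_level
  class(out) <- c("stroop_components", class(out))
  attr(out, "measure") <- fit$measure
  out
}

#' @export
print.stroop_fit <- function(x, ...) {
  cat("<stroop_fit> measure: ", x$measure, "\n  random structure: ",
      paste(x$structure, collapse = " + "),
      if (x$singular) "  [singular]", if (!x$converged) "  [non-convergent]",
      "\n", sep = "")
  print(fixef_coefs(x))
  invisible(x)
}
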