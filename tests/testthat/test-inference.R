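# balanced measure data with known per-condition means and participant shifts
balanced_data <- function(n_p = 6, n_t = 4, means = NULL, p_sd = 20,
                          noise = 10, slope_sd = 0, seed = 71) {
  set.seed(seed)
  if (is.null(means)) {
    means <- setNames(c(1189, 1111, 1075, 1070, 1045, 1029), stroop_conditions())
  }
  b_p <- rnorm(n_p, 0, p_sd)
  b_sl <- rnorm(n_p, 0, slope_sd)   # extra by-participant standard-incongruent shift
  d <- tidyr::expand_grid(
    participant_id = sprintf("P%03d", 1:n_p),
    condition = stroop_conditions(),
    rep = 1:n_t
  )
  i <- as.integer(factor(d$participant_id))
  d$value <- means[d$condition] + b_p[i] +
    b_sl[i] * (d$condition == "standard_incongruent") +
    rnorm(nrow(d), 0, noise)
  d
}

test_that("noiseless balanced data is recovered exactly", {
  d <- balanced_data(p_sd = 0, noise = 0)
  fit <- fit_lmm(d, "value")
  # zero residual variance: the covariance machinery warns that the fit is
  # exact, which is precisely the point of this case
  mm <- suppressWarnings(marginal_means(fit))
  expect_equal(setNames(mm$mean, mm$condition)[stroop_conditions()],
               setNames(c(1189, 1111, 1075, 1070, 1045, 1029),
                        stroop_conditions()),
               tolerance = 1e-6)
  cc <- suppressWarnings(component_contrasts(fit))
  expect_equal(cc$estimate[cc$component == "total_stroop"], 160, tolerance = 1e-6)
})

test_that("single-participant data degenerates to the least-squares fit", {
  d <- balanced_data(n_p = 1, p_sd = 0)
  fit <- fit_lmm(d, "value")
  expect_s3_class(fit$model, "lm")
  ols <- stats::lm(value ~ condition_factor(condition), data = d)
  cellm <- c(tapply(d$value, d$condition, mean))
  mm <- marginal_means(fit)
  expect_equal(setNames(mm$mean, mm$condition)[names(cellm)], cellm)
  cc <- component_contrasts(fit)
  expect_equal(cc$estimate[cc$component == "interference"],
               unname(cellm["standard_incongruent"] - cellm["neutral"]))
  expect_equal(unique(cc$df), stats::df.residual(ols))
})

test_that("structure selection responds to the true random-effect structure", {
  # with one observation per cell only the intercept is estimable
  pe_like <- balanced_data(n_t = 1)
  expect_identical(select_random_structure(pe_like, "value"), "intercept")

  # zero slope variance: intercept-only wins in the majority of replicates
  picks <- vapply(1:5, function(s) {
    d <- balanced_data(n_p = 12, n_t = 6, slope_sd = 0, seed = 500 + s)
    length(select_random_structure(d, "value"))
  }, numeric(1))
  expect_gt(mean(picks == 1), 0.5)

  # a large standard-incongruent slope variance should be retained
  keeps <- vapply(1:5, function(s) {
    d <- balanced_data(n_p = 12, n_t = 6, slope_sd = 60, seed = 600 + s)
    "standard_incongruent" %in% select_random_structure(d, "value")
  }, logical(1))
  expect_gt(mean(keeps), 0.5)
})

test_that("marginal means and contrasts agree with the emmeans route", {
  skip_if_not_installed("emmeans")
  d <- balanced_data(n_p = 8, n_t = 4, p_sd = 30, noise = 15)
  fit <- fit_lmm(d, "value", c("intercept", "standard_incongruent"))
  mm <- marginal_means(fit)
  emg <- emmeans::emmeans(fit$model, "condition", lmer.df = "satterthwaite")
  em <- as.data.frame(emg)
  ord <- match(mm$condition, em$condition)
  expect_equal(mm$mean, em$emmean[ord], tolerance = 1e-9)
  expect_equal(mm$se, em$SE[ord], tolerance = 1e-9)
  expect_equal(mm$df, em$df[ord], tolerance = 1e-3)

  cc <- component_contrasts(fit, ci_level = 0.99)
  w <- (em$condition == "standard_incongruent") -
    (em$condition == "standard_congruent")
  ec <- as.data.frame(emmeans::contrast(emg, method = list(total_stroop = w)))
  tot <- cc[cc$component == "total_stroop", ]
  expect_equal(tot$estimate, ec$estimate, tolerance = 1e-9)
  expect_equal(tot$se, ec$SE, tolerance = 1e-9)
})

test_that("component estimates are invariant to the dummy reference level", {
  d <- balanced_data(n_p = 6, n_t = 4)
  f_neutral <- fit_lmm(d, "value")
  f_other <- fit_lmm(d, "value", reference = "standard_congruent")
  # coefficients differ...
  expect_false(isTRUE(all.equal(unname(lme4::fixef(f_neutral$model)),
                                unname(lme4::fixef(f_other$model)))))
  # ...but every component estimate and SE is unchanged
  c1 <- component_contrasts(f_neutral, 0.99)
  c2 <- component_contrasts(f_other, 0.99)
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-8)
  expect_equal(c1$se, c2$se, tolerance = 1e-8)
})

test_that("contrast standard errors agree with a parametric bootstrap", {
  d <- balanced_data(n_p = 8, n_t = 4, p_sd = 25, noise = 12, seed = 81)
  fit <- fit_lmm(d, "value")
  cc <- component_contrasts(fit)
  se_model <- cc$se[cc$component == "total_stroop"]
  set.seed(82)
  sims <- stats::simulate(fit$model, nsim = 200)
  boots <- vapply(seq_len(200), function(i) {
    m <- suppressMessages(suppressWarnings(lme4::refit(fit$model, sims[[i]])))
    b <- lme4::fixef(m)
    b["conditionstandard_incongruent"] - b["conditionstandard_congruent"]
  }, numeric(1))
  expect_lt(abs(sd(boots) - se_model) / se_model, 0.15)
})

test_that("fitted models on study-calibrated data recover RT structure", {
  sh <- shared_data()
  fit <- fit_lmm(sh$measures, "rt_ms")
  expect_true(fit$converged)
  mm <- marginal_means(fit)
  neutral <- mm$mean[mm$condition == "neutral"]
  # the configured neutral mean is 1070 ms; 10 participants give a wide but
  # informative interval
  expect_lt(abs(neutral - 1070) / mm$se[mm$condition == "neutral"], 3)
  cc <- component_contrasts(fit, 0.99)
  expect_gt(cc$estimate[cc$component == "total_stroop"], 0)
  res <- additivity_residuals(cc)
  expect_lt(max(abs(res$residual)), 1e-10)
})
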