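test_that("signed deviation matches its closed form and the rotation oracle", {
  # collinear points lie on y = 1.5 x
  expect_equal(signed_deviation(0.4, 0.6), 0)
  expect_equal(signed_deviation(0, 1), 1 / sqrt(3.25))
  expect_equal(signed_deviation(1, 0), -1.5 / sqrt(3.25))

  set.seed(31)
  x <- runif(500, -1, 2); y <- runif(500, -1, 3)
  expect_equal(signed_deviation(x, y), oracle_signed_deviation(x, y),
               tolerance = 1e-12)
})

test_that("max deviation above agrees with a dense-sampling oracle on an arc", {
  expect_equal(max_deviation_above(c(0, 0.5, 1), c(0, 0.75, 1.5)), 0)

  # circular-arc detour above the direct path with an analytic apex
  t <- seq(0, 1, length.out = 2001)
  x <- t - 0.3 * sin(pi * t) * 1.5 / sqrt(3.25)
  y <- 1.5 * t + 0.3 * sin(pi * t) * 1 / sqrt(3.25)
  # by construction the path is the direct line plus 0.3 sin(pi t) along the
  # upward normal, so the maximum deviation is exactly 0.3
  expect_equal(max_deviation_above(x, y), 0.3, tolerance = 1e-6)
  expect_equal(max_deviation_above(x, y),
               max(oracle_signed_deviation(x, y)), tolerance = 1e-12)
})

test_that("initiation time scans for the first threshold crossing", {
  # stationary for 150 ms, then movement
  t_ms <- seq(0, 300, by = 10)
  x <- c(rep(0, 15), seq(1, 16))
  y <- rep(0, 31)
  expect_equal(initiation_time(t_ms, x, y), 150)
  # movement on the first post-click sample
  expect_equal(initiation_time(c(0, 10, 20), c(0, 2, 4), c(0, 0, 0)), 10)
  # threshold crossing against a hand-built displacement series
  disp <- c(0, 1, 2, 4, 4.9, 5.2, 9)
  idx_oracle <- which(disp > 5)[1]
  expect_equal(initiation_time(seq(0, 60, 10), disp, rep(0, 7),
                               movement_threshold = 5),
               (idx_oracle - 1) * 10)
  # no movement at all: trial duration, flagged
  it <- initiation_time(c(0, 10, 20), c(0, 0, 0), c(0, 0, 0))
  expect_equal(as.numeric(it), 20)
  expect_true(attr(it, "no_movement"))
})

test_that("response time is the click-to-selection interval, alignment-invariant", {
  expect_equal(response_time(c(0, 500)), 500)
  expect_equal(response_time(c(120, 309, 1309)), 1189)
  sh <- shared_data()
  rt_raw <- sh$dat$samples |>
    dplyr::group_by(participant_id, trial_index) |>
    dplyr::summarise(rt = response_time(time_ms), .groups = "drop")
  rt_aligned <- sh$aligned |>
    dplyr::group_by(participant_id, trial_index) |>
    dplyr::summarise(rt = response_time(time_ms), .groups = "drop")
  joined <- dplyr::inner_join(rt_raw, rt_aligned,
                              by = c("participant_id", "trial_index"))
  expect_equal(joined$rt.x, joined$rt.y)
})

test_that("profiles satisfy the endpoint contracts and bound md_above", {
  sh <- shared_data()
  ends <- sh$profiles |>
    dplyr::filter(step %in% c(1, 101)) |>
    tidyr::pivot_wider(names_from = step, values_from = c(deviation, x_coordinate))
  expect_lt(max(abs(ends$deviation_1)), 1e-12)
  expect_lt(max(abs(ends$deviation_101)), 1e-12)
  expect_lt(max(abs(ends$x_coordinate_1)), 1e-12)
  expect_lt(max(abs(ends$x_coordinate_101 - 1)), 1e-12)

  # time-normalized profiles subsample the raw path, so their maximum cannot
  # exceed the raw-resolution md_above (up to interpolation tolerance)
  prof_max <- sh$profiles |>
    dplyr::group_by(participant_id, trial_index) |>
    dplyr::summarise(pmax = max(deviation), .groups = "drop") |>
    dplyr::inner_join(sh$measures, by = c("participant_id", "trial_index"))
  expect_true(all(prof_max$pmax <= prof_max$md_above + 1e-9))
})

test_that("a known mid-course excursion appears at the right step", {
  x <- c(960, 820, 1660)   # crosses leftward before heading to green
  y <- c(940, 560, 180)
  tr <- manual_trial(x, y, time_ms = c(0, 500, 1000))
  a <- remap_and_align(tr$samples, tr$trials, screen_layout())
  p <- trajectory_profiles(time_normalize(a))
  expect_equal(min(p$x_coordinate), (820 - 960) / 700)
  expect_equal(p$step[which.min(p$x_coordinate)], 51)
})

test_that("mirroring an aligned path about the direct line negates deviations", {
  sh <- shared_data()
  one <- time_normalize(
    sh$aligned |> dplyr::filter(participant_id == "P002") |>
      dplyr::filter(trial_index == min(trial_index))
  )
  u <- c(1, 1.5) / sqrt(3.25)
  R <- matrix(c(2 * u[1]^2 - 1, 2 * u[1] * u[2],
                2 * u[1] * u[2], 2 * u[2]^2 - 1), 2, 2)
  xy <- as.matrix(one[, c("x", "y")]) %*% t(R)
  mirrored <- dplyr::mutate(one, x = xy[, 1], y = xy[, 2])
  expect_equal(trajectory_profiles(mirrored)$deviation,
               -trajectory_profiles(one)$deviation, tolerance = 1e-12)
})

test_that("condition ordering of mean MD follows the calibrated gradient", {
  sh <- shared_data()
  md <- sh$measures |>
    dplyr::group_by(condition) |>
    dplyr::summarise(md = mean(md_above)) |>
    tibble::deframe()
  expect_gt(md[["standard_incongruent"]], md[["nonresponse_set"]])
  expect_gt(md[["standard_incongruent"]], md[["associated_incongruent"]])
  expect_gt(min(md[["nonresponse_set"]], md[["associated_incongruent"]]),
            md[["standard_congruent"]])
  expect_gt(md[["neutral"]], md[["standard_congruent"]])
  # calibrated magnitude: mean MD-above for standard congruent trials sits
  # near 0.43 normalized units
  expect_lt(abs(md[["standard_congruent"]] - 0.43), 0.1)
})
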