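make_cell <- function(rts, participant = "P001", condition = "neutral",
                      status = "correct") {
  tibble::tibble(
    participant_id = participant, trial_index = seq_along(rts),
    condition = condition, status = status, rt_ms = rts, it_ms = 150
  )
}

test_that("the 3 SD rule removes exactly the trials a brute-force scan flags", {
  set.seed(9)
  rts <- rnorm(10, 1000, 50)
  rts[10] <- mean(rts[1:9]) + 5 * sd(rts[1:9])
  kept <- filter_trials(make_cell(rts))
  # oracle: recompute cell mean/SD on all correct trials and scan
  flag <- abs(rts - mean(rts)) > 3 * sd(rts)
  expect_setequal(kept$trial_index, which(!flag))
  rep <- exclusion_report(kept)
  expect_equal(rep$counts$n[rep$counts$rule == "rt_outlier"], sum(flag))
  expect_equal(rep$counts$pct, 100 * rep$counts$n / 10)
})

test_that("omissions and errors are removed before the RT rule, and edge cells pass through", {
  all_to <- make_cell(rep(1000, 5), status = "timeout")
  kept <- filter_trials(all_to)
  expect_equal(nrow(kept), 0)
  expect_equal(exclusion_report(kept)$counts$n, c(5, 0, 0))

  # an extreme RT on an error trial must not widen the correct-trial SD
  mix <- dplyr::bind_rows(make_cell(c(rep(1000, 9), 1150)),
                          make_cell(9999, status = "error") |>
                            dplyr::mutate(trial_index = 99L))
  kept <- filter_trials(mix)
  expect_false(99 %in% kept$trial_index)
  expect_setequal(kept$trial_index,
                  which(abs(mix$rt_ms[1:10] - mean(mix$rt_ms[1:10])) <=
                          3 * sd(mix$rt_ms[1:10])))

  # degenerate SD = 0: nothing removed
  expect_equal(nrow(filter_trials(make_cell(rep(800, 6)))), 6)
  # singleton cell: outlier rule skipped, trial kept and logged
  kept1 <- filter_trials(make_cell(5000))
  expect_equal(nrow(kept1), 1)
  expect_equal(nrow(exclusion_report(kept1)$small_cells), 1)
})

test_that("filtering is idempotent", {
  sh <- shared_data()
  once <- filter_trials(sh$dat$trials)
  twice <- filter_trials(once)
  expect_equal(nrow(twice), nrow(once))
  expect_true(all(exclusion_report(twice)$counts$n == 0))
})

test_that("alignment anchors every trajectory at (0,0) and (1,1.5)", {
  sh <- shared_data()
  ends <- sh$aligned |>
    dplyr::group_by(participant_id, trial_index) |>
    dplyr::summarise(x0 = dplyr::first(x), y0 = dplyr::first(y),
                     x1 = dplyr::last(x), y1 = dplyr::last(y),
                     .groups = "drop")
  expect_equal(max(abs(ends$x0)), 0)
  expect_equal(max(abs(ends$y0)), 0)
  expect_lt(max(abs(ends$x1 - 1)), 1e-12)
  expect_lt(max(abs(ends$y1 - 1.5)), 1e-12)
})

test_that("a left-side trial and its exact mirror align identically", {
  layout <- screen_layout()
  # rightward trial toward green, and its mirror toward red
  xr <- c(960, 1100, 1350, 1660)
  y <- c(940, 700, 400, 180)
  right <- manual_trial(xr, y, correct_box = "green")
  left <- manual_trial(2 * 960 - xr, y, correct_box = "red")
  ar <- remap_and_align(right$samples, right$trials, layout)
  al <- remap_and_align(left$samples, left$trials, layout)
  expect_false(any(ar$remapped))
  expect_true(all(al$remapped))
  expect_equal(al$x, ar$x)
  expect_equal(al$y, ar$y)
})

test_that("alignment matches the closed-form affine map on a known path", {
  layout <- screen_layout()
  tr <- manual_trial(c(960, 1200, 1660), c(940, 500, 180))
  out <- remap_and_align(tr$samples, tr$trials, layout)
  expect_equal(out$x, (c(960, 1200, 1660) - 960) / (1660 - 960) * 1)
  expect_equal(out$y, (c(940, 500, 180) - 940) / (180 - 940) * 1.5)
  # intermediate y flips sign direction: upward progress is positive
  expect_true(all(diff(out$y) > 0))

  degen <- manual_trial(c(960, 960), c(940, 940))
  expect_error(remap_and_align(degen$samples, degen$trials, layout),
               class = "strooptrace_alignment_error")
})

test_that("time normalization returns 101 interpolated steps spanning the trial", {
  tr <- manual_trial(c(960, 1660), c(940, 180), time_ms = c(0, 500))
  a <- remap_and_align(tr$samples, tr$trials, screen_layout())
  tn <- time_normalize(a)
  expect_equal(nrow(tn), 101)
  expect_equal(tn$step, 1:101)
  # straight 2-sample path: 101 collinear, equally spaced points
  expect_equal(tn$x, seq(0, 1, length.out = 101))
  expect_equal(tn$y, seq(0, 1.5, length.out = 101))
  expect_equal(unique(tn$total_duration_ms), 500)

  # piecewise path with a kink: hand linear interpolation at probe steps
  kink <- manual_trial(c(960, 1100, 1660), c(940, 400, 180),
                       time_ms = c(0, 400, 1000))
  ak <- remap_and_align(kink$samples, kink$trials, screen_layout())
  tk <- time_normalize(ak)
  probe <- function(t_ms) {
    i <- findInterval(t_ms, c(0, 400, 1000), rightmost.closed = TRUE)
    f <- (t_ms - c(0, 400)[i]) / c(400, 600)[i]
    x <- c(0, 140 / 700, 1); y <- c(0, 540 / 760 * 1.5, 1.5)
    c(x[i] + f * (x[i + 1] - x[i]), y[i] + f * (y[i + 1] - y[i]))
  }
  for (s in c(26, 51, 76)) {
    t_ms <- (s - 1) / 100 * 1000
    expect_equal(c(tk$x[s], tk$y[s]), probe(t_ms), tolerance = 1e-12)
  }

  # an already time-uniform trajectory is returned unchanged
  u <- time_normalize(ak, n_steps = 3)
  again <- tibble::tibble(participant_id = "P001", trial_index = 1L,
                          time_ms = c(0, 500, 1000), x = u$x, y = u$y)
  expect_equal(time_normalize(again, n_steps = 3)[c("x", "y")],
               u[c("x", "y")])
})

test_that("space normalization spaces 100 points evenly along the arc", {
  # L-shaped path, legs 3 and 4 in aligned units scaled onto the anchors
  tr <- manual_trial(c(960, 960 + 700, 960 + 700), c(940, 940, 180))
  a <- remap_and_align(tr$samples, tr$trials, screen_layout())
  sn <- space_normalize(a)
  expect_equal(nrow(sn), 100)
  # aligned legs: (0,0)->(1,0) length 1, then (1,0)->(1,1.5) length 1.5, so a
  # point's arc position along the polyline is x on the first leg and 1 + y
  # on the second; increments must be equal at 2.5/99
  arc_pos <- ifelse(sn$y <= 1e-12, sn$x, 1 + sn$y)
  expect_equal(diff(arc_pos), rep(2.5 / 99, 99), tolerance = 1e-9)
  expect_equal(c(sn$x[1], sn$y[1]), c(0, 0))
  expect_equal(c(sn$x[100], sn$y[100]), c(1, 1.5))

  # dwell samples (repeated points) do not change the result
  dup <- tr
  dup$samples <- dup$samples[c(1, 1, 1, 2, 2, 3), ] |>
    dplyr::mutate(time_ms = seq(0, 50, length.out = 6))
  ad <- remap_and_align(dup$samples, dup$trials, screen_layout())
  sd_ <- space_normalize(ad)
  expect_equal(sd_$x, sn$x)
  expect_equal(sd_$y, sn$y)

  # straight segment: equally spaced collinear points
  st <- manual_trial(c(960, 1660), c(940, 180))
  ss <- space_normalize(remap_and_align(st$samples, st$trials, screen_layout()))
  expect_equal(ss$x, seq(0, 1, length.out = 100))
})

test_that("both normalizers commute with mirroring about the direct path", {
  sh <- shared_data()
  one <- sh$aligned |>
    dplyr::filter(participant_id == "P001",
                  trial_index == min(trial_index[participant_id == "P001"]))
  # mirror about the direct line y = 1.5 x (reflection matrix applied to (x,y))
  mirror <- function(d) {
    u <- c(1, 1.5) / sqrt(3.25)
    R <- matrix(c(2 * u[1]^2 - 1, 2 * u[1] * u[2],
                  2 * u[1] * u[2], 2 * u[2]^2 - 1), 2, 2)
    xy <- as.matrix(d[, c("x", "y")]) %*% t(R)
    dplyr::mutate(d, x = xy[, 1], y = xy[, 2])
  }
  tn_then_mirror <- mirror(time_normalize(one))
  mirror_then_tn <- time_normalize(mirror(one))
  expect_equal(tn_then_mirror$x, mirror_then_tn$x, tolerance = 1e-12)
  expect_equal(tn_then_mirror$y, mirror_then_tn$y, tolerance = 1e-12)
  sn_then_mirror <- mirror(space_normalize(one))
  mirror_then_sn <- space_normalize(mirror(one))
  expect_equal(sn_then_mirror$x, mirror_then_sn$x, tolerance = 1e-9)
  expect_equal(sn_then_mirror$y, mirror_then_sn$y, tolerance = 1e-9)
})
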