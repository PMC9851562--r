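#' Simulate a mouse-tracking Stroop dataset with known ground truth
#'
#' Draws `n_participants x 6 conditions x n_trials_per_condition` trials from
#' the two-attractor co-activation model described in [sim_config()]. Each
#' trial dwells at the start-box centre for an initiation delay, then moves in
#' discrete 1/`sample_rate` steps toward a blended target
#' `T(t) = w(t) * incorrect_box + (1 - w(t)) * correct_box`; the weight `w`
#' starts at the condition's pull amplitude (raised on partial-error-regime
#' trials) and decays geometrically, and isotropic Gaussian positional noise
#' is added at every step except the last, so the cursor ends exactly on its
#' final target. Participants contribute an additive random effect on mean RT
#' and on pull amplitude. Error and timeout trials are generated by
#' independent Bernoulli draws so that downstream exclusion rules have
#' something to remove.
#'
#' @param config A [sim_config()] object.
#' @param layout A [screen_layout()] object.
#' @param include_samples If `FALSE`, skip trajectory generation and return
#'   trial metadata only (useful for large chronometric simulation studies).
#' @return A `stroop_data` list with elements `trials` (one row per trial:
#'   `participant_id`, `trial_index`, `condition`, `word`, `ink`,
#'   `correct_box`, `chosen_box`, `status`, `rt_ms`, `it_ms`, plus the
#'   ground-truth columns `pe_regime` and `pull_w0`), `samples` (long tibble:
#'   `participant_id`, `trial_index`, `time_ms`, `x_px`, `y_px`), `layout`
#'   and `config`.
#' @export
#' @examples
#' dat <- simulate_trials(sim_config(n_participants = 2, seed = 1))
#' dat$trials
simulate_trials <- function(config, layout = screen_layout(),
                            include_samples = TRUE) {
  validate_sim_config(config)
  validate_screen_layout(layout)
  if (!is.null(config$seed)) set.seed(config$seed)

  conds <- stroop_conditions()
  n_p <- config$n_participants
  n_t <- config$n_trials_per_condition
  dt <- 1000 / config$sample_rate

  participants <- sprintf("P%03d", seq_len(n_p))
  b_rt <- setNames(rnorm(n_p, 0, config$participant_sd_rt), participants)
  b_pull <- setNames(rnorm(n_p, 0, config$participant_sd_pull), participants)

  stim <- stimulus_table()
  trials <- tidyr::expand_grid(
    participant_id = participants,
    condition = conds,
    rep = seq_len(n_t)
  )
  n <- nrow(trials)

  # stimulus word cycles through the condition's four items; ink is the
  # word's own colour (congruent), its pair partner (incongruent), or a
  # colour drawn from the word's assigned pair (neutral / non-response set)
  word_idx <- ((trials$rep - 1L) %% 4L) + 1L
  stim <- dplyr::mutate(stim, .widx = stats::ave(seq_len(nrow(stim)),
                                                 stim$condition, FUN = seq_along))
  stim_rows <- dplyr::left_join(
    dplyr::mutate(trials, .widx = word_idx), stim,
    by = c("condition", ".widx")
  )
  trials$word <- stim_rows$word
  pairs <- colour_pairs()
  pick <- 1L + (runif(n) < 0.5)
  pair_draw <- vapply(pairs, `[`, character(1), 1)[stim_rows$pair]
  alt <- vapply(pairs, `[`, character(1), 2)[stim_rows$pair]
  pair_draw[pick == 2L] <- alt[pick == 2L]
  trials$ink <- dplyr::case_when(
    trials$condition %in% c("standard_congruent", "associated_congruent") ~
      stim_rows$word_colour,
    trials$condition %in% c("standard_incongruent", "associated_incongruent") ~
      paired_colour(stim_rows$word_colour),
    TRUE ~ pair_draw
  )
  trials$correct_box <- trials$ink

  # timing: initiation delay truncated to [40, deadline]; mean RT additive in
  # condition offset and participant effect, with a mean-one lognormal
  # trial-level multiplier so configured means are exact marginal means
  trials$it_ms <- truncnorm(n, config$it_mean, config$it_sd,
                            lo = 40, hi = config$initiation_deadline)
  mu_rt <- config$rt_base + config$rt_offsets[trials$condition] +
    b_rt[trials$participant_id]
  s <- sqrt(log1p(config$rt_cv^2))
  mult <- exp(rnorm(n, -s^2 / 2, s))
  trials$rt_ms <- pmax(unname(mu_rt) * mult, trials$it_ms + 5 * dt)

  # trial regime and outcome draws
  trials$pe_regime <- runif(n) < config$pull_prob[trials$condition]
  w0_base <- pmin(pmax(config$pull_amplitude[trials$condition] +
                         b_pull[trials$participant_id], 0), 1)
  trials$pull_w0 <- ifelse(trials$pe_regime, config$pe_pull_amplitude,
                           unname(w0_base))
  is_error <- runif(n) < config$error_prob
  is_timeout <- (runif(n) < config$omission_prob) | (trials$rt_ms >= config$timeout)
  trials$rt_ms <- pmin(trials$rt_ms, config$timeout)
  trials$status <- dplyr::case_when(
    is_timeout ~ "timeout",
    is_error ~ "error",
    TRUE ~ "correct"
  )
  trials$chosen_box <- dplyr::case_when(
    trials$status == "timeout" ~ NA_character_,
    trials$status == "error" ~ paired_colour(trials$ink),
    TRUE ~ trials$ink
  )
  trials$trial_index <- stats::ave(seq_len(n), trials$participant_id,
                                   FUN = seq_along)
  trials <- dplyr::select(
    dplyr::as_tibble(trials),
    "participant_id", "trial_index", "condition", "word", "ink",
    "correct_box", "chosen_box", "status", "rt_ms", "it_ms",
    "pe_regime", "pull_w0"
  )

  samples <- if (include_samples) {
    simulate_samples(trials, config, layout, dt)
  } else {
    tibble::tibble(participant_id = character(), trial_index = integer(),
                   time_ms = numeric(), x_px = numeric(), y_px = numeric())
  }

  structure(list(trials = trials, samples = samples, layout = layout,
                 config = config),
            class = "stroop_data")
}

# discrete-time blended-attractor motion, vectorized across trials: one pass
# over sample indices updating all trials' positions simultaneously
simulate_samples <- function(trials, config, layout, dt) {
  n <- nrow(trials)
  # movement target is the chosen box when a response was made, else the
  # correct box; the competing attractor is always its mirrored partner
  goal_col <- ifelse(is.na(trials$chosen_box), trials$correct_box,
                     trials$chosen_box)
  goal <- t(box_center(layout, goal_col))        # n x 2
  rival <- t(box_center(layout, paired_colour(goal_col)))
  start <- matrix(layout$start_center, n, 2, byrow = TRUE)

  n_steps <- floor(trials$rt_ms / dt) + 1L       # grid samples incl. t = 0
  has_tail <- (n_steps - 1L) * dt < trials$rt_ms # off-grid final sample
  total <- n_steps + has_tail
  # index of the first sample strictly after the initiation delay
  first_move <- pmin(floor(trials$it_ms / dt) + 2L, total)
  decay <- ifelse(trials$pe_regime, config$pe_pull_decay, config$pull_decay)

  m_steps <- pmax(total - first_move + 1L, 1L)   # movement updates per trial
  max_j <- max(total)
  X <- matrix(NA_real_, n, max_j)
  Y <- matrix(NA_real_, n, max_j)
  X[, 1] <- start[, 1]
  Y[, 1] <- start[, 2]
  px <- start[, 1]
  py <- start[, 2]
  for (j in 2:max_j) {
    alive <- total >= j
    moving <- alive & first_move <= j
    last <- total == j
    idx <- pmax(j - first_move + 1L, 1L)         # movement step number
    # attractor weight decays geometrically; the response itself is at the
    # goal box, so the final step's target is the goal exactly
    wj <- ifelse(last, 0, trials$pull_w0 * decay^(idx - 1))
    tx <- wj * rival[, 1] + (1 - wj) * goal[, 1]
    ty <- wj * rival[, 2] + (1 - wj) * goal[, 2]
    # bell-shaped speed profile (peak late for velocity_skew > 1), with an
    # endpoint-anchoring floor so the cursor lands on its final target
    bell <- sin(pi * pmin(idx / m_steps, 1)^config$velocity_skew)^2
    remaining <- pmax(total - j + 1L, 1L)
    frac <- pmax(config$pursuit_gain * bell, 1 / remaining)
    noise <- config$noise_sd * !last             # endpoint lands on target
    nx <- px + (tx - px) * frac + rnorm(n, 0, 1) * noise
    ny <- py + (ty - py) * frac + rnorm(n, 0, 1) * noise
    px <- ifelse(moving, nx, px)
    py <- ifelse(moving, ny, py)
    X[alive, j] <- px[alive]
    Y[alive, j] <- py[alive]
  }

  rows <- rep(seq_len(n), total)
  cols <- sequence(total)
  t_ms <- pmin((cols - 1) * dt, trials$rt_ms[rows])
  tibble::tibble(
    participant_id = trials$participant_id[rows],
    trial_index = trials$trial_index[rows],
    time_ms = t_ms,
    x_px = X[cbind(rows, cols)],
    y_px = Y[cbind(rows, cols)]
  )
}

truncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' @export
print.stroop_data <- function(x, ...) {
  cat("<stroop_data> ", nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$trials$participant_id), " participants, ",
      nrow(x$samples), " cursor samples\n", sep = "")
  print(dplyr::count(x$trials, .data$condition, .data$status))
  invisible(x)
}
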