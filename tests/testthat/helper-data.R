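# Shared fixtures, built in code. The moderate dataset is simulated once per
# test run and reused by the preprocessing, measures, clustering and
# inference tests.

named6 <- function(...) {
  v <- c(...)
  if (length(v) == 1) v <- rep(v, 6)
  setNames(v, stroop_conditions())
}

# a deterministic, effect-free configuration for structural tests
flat_config <- function(n_participants = 2, n_trials = 4, seed = 1, ...) {
  sim_config(
    n_participants = n_participants, n_trials_per_condition = n_trials,
    rt_offsets = named6(0), pull_amplitude = named6(0), pull_prob = named6(0),
    participant_sd_rt = 0, participant_sd_pull = 0, rt_cv = 0,
    noise_sd = 0, error_prob = 0, omission_prob = 0, it_sd = 1e-9,
    seed = seed, ...
  )
}

shared_env <- new.env()

# study-calibrated simulation at reduced size, preprocessed once
shared_data <- function() {
  if (is.null(shared_env$dat)) {
    dat <- simulate_trials(sim_config(n_participants = 10, seed = 424242))
    kept <- filter_trials(dat$trials)
    aligned <- remap_and_align(dat$samples, kept, dat$layout)
    shared_env$dat <- dat
    shared_env$kept <- kept
    shared_env$aligned <- aligned
    shared_env$tnorm <- time_normalize(aligned)
    shared_env$snorm <- space_normalize(aligned)
    shared_env$measures <- trial_measures(aligned, kept)
    shared_env$profiles <- trajectory_profiles(shared_env$tnorm, kept)
  }
  as.list(shared_env)
}

# build a samples/trials pair from explicit coordinate vectors
manual_trial <- function(x, y, time_ms = seq(0, by = 10, length.out = length(x)),
                         participant_id = "P001", trial_index = 1L,
                         condition = "neutral", correct_box = "green") {
  list(
    trials = tibble::tibble(
      participant_id = participant_id, trial_index = trial_index,
      condition = condition, word = "dog", ink = correct_box,
      correct_box = correct_box, chosen_box = correct_box,
      status = "correct", rt_ms = max(time_ms), it_ms = 0
    ),
    samples = tibble::tibble(
      participant_id = participant_id, trial_index = trial_index,
      time_ms = time_ms, x_px = x, y_px = y
    )
  )
}

# brute-force deviation oracle: rotate coordinates so the direct path lies on
# the positive x-axis; the deviation is then simply the rotated y-coordinate
oracle_signed_deviation <- function(x, y, start = c(0, 0), end = c(1, 1.5)) {
  theta <- atan2(end[2] - start[2], end[1] - start[1])
  -sin(theta) * (x - start[1]) + cos(theta) * (y - start[2])
}
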