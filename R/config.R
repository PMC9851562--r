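#' Configuration of the synthetic mouse-tracking Stroop generator
#'
#' The generator draws trials from a two-attractor co-activation model: after
#' an initiation delay the cursor moves toward a blended target
#' `T(t) = w(t) * incorrect_box + (1 - w(t)) * correct_box`, where the
#' incorrect-attractor weight starts at `pull_amplitude[condition]` and decays
#' geometrically, so trajectories bow toward the incorrect-response side
#' mid-movement and finish at the correct box. A `pull_prob[condition]`
#' fraction of trials are partial-error-regime trials: their initial weight is
#' raised to `pe_pull_amplitude` and decays at the slower `pe_pull_decay`, so
#' the cursor crosses materially onto the incorrect side before correcting.
#'
#' Default effect sizes are calibrated to the condition means of the study
#' design this generator emulates: response-time offsets relative to the
#' colour-neutral baseline of +119/+41/+5/0/-25/-41 ms (standard incongruent,
#' non-response set, associated incongruent, neutral, associated congruent,
#' standard congruent), partial-error-regime probabilities of
#' 36.7/26.1/28.6/24.9/24.0/22.3 %, and pull amplitudes graded the same way so
#' mean maximum deviation spans roughly 0.43-0.68 normalized units.
#'
#' @param n_participants Number of simulated participants.
#' @param n_trials_per_condition Trials per participant in each of the six
#'   conditions (default 32).
#' @param sample_rate Cursor sampling rate in Hz (default 100).
#' @param rt_base Mean response time of the neutral condition (ms).
#' @param rt_offsets Named numeric, additive ground-truth condition effects on
#'   mean RT (ms); names are the six condition labels, neutral must be 0.
#' @param pull_amplitude Named numeric in `[0, 1]`, initial incorrect-attractor
#'   weight per condition on ordinary trials.
#' @param pull_prob Named numeric in `[0, 1]`, probability that a trial is in
#'   the partial-error regime, per condition.
#' @param pull_decay Geometric decay factor per sample of the attractor weight
#'   on ordinary trials.
#' @param pe_pull_amplitude,pe_pull_decay Initial weight and decay on
#'   partial-error-regime trials (higher weight, slower decay).
#' @param pursuit_gain Fraction of the gap to the blended target closed per
#'   sample at peak movement speed.
#' @param velocity_skew Exponent skewing the bell-shaped velocity profile;
#'   values above 1 place peak speed late in the movement, which moves the
#'   deviation peak toward 60 percent of total response duration.
#' @param it_mean,it_sd Mean and SD of the initiation delay (ms); draws are
#'   truncated to `[40, initiation_deadline]`.
#' @param participant_sd_rt SD of the by-participant additive RT effect (ms).
#' @param participant_sd_pull SD of the by-participant additive effect on pull
#'   amplitude (results truncated to `[0, 1]`).
#' @param rt_cv Coefficient of variation of the mean-one lognormal trial-level
#'   RT multiplier.
#' @param noise_sd SD of isotropic Gaussian positional noise per sample (px).
#' @param timeout Response deadline (ms, default 2500).
#' @param initiation_deadline Initiation deadline (ms, default 500).
#' @param error_prob,omission_prob Per-trial probabilities of an incorrect
#'   response and of a timeout.
#' @param seed Optional integer seed; when set, `simulate_trials()` is
#'   byte-reproducible.
#' @return A validated `sim_config` object (list).
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 4, seed = 1)
#' cfg$rt_offsets
sim_config <- function(n_participants = 80,
                       n_trials_per_condition = 32,
                       sample_rate = 100,
                       rt_base = 1070,
                       rt_offsets = c(
                         standard_incongruent = 119,
                         nonresponse_set = 41,
                         associated_incongruent = 5,
                         neutral = 0,
                         associated_congruent = -25,
                         standard_congruent = -41
                       ),
                       pull_amplitude = c(
                         standard_incongruent = 0.55,
                         nonresponse_set = 0.39,
                         associated_incongruent = 0.37,
                         neutral = 0.34,
                         associated_congruent = 0.32,
                         standard_congruent = 0.29
                       ),
                       pull_prob = c(
                         standard_incongruent = 0.367,
                         nonresponse_set = 0.261,
                         associated_incongruent = 0.286,
                         neutral = 0.249,
                         associated_congruent = 0.240,
                         standard_congruent = 0.223
                       ),
                       pull_decay = 0.985,
                       pe_pull_amplitude = 0.92,
                       pe_pull_decay = 0.992,
                       pursuit_gain = 0.25,
                       velocity_skew = 1.8,
                       it_mean = 168,
                       it_sd = 40,
                       participant_sd_rt = 110,
                       participant_sd_pull = 0.06,
                       rt_cv = 0.18,
                       noise_sd = 4,
                       timeout = 2500,
                       initiation_deadline = 500,
                       error_prob = 0.0058,
                       omission_prob = 0.0034,
                       seed = NULL) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  conds <- stroop_conditions()
  fail <- function(field, why) {
    abort(paste0("Invalid `", field, "`: ", why), class = "strooptrace_config_error")
  }
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min || v != round(v)) {
      fail(field, paste0("must be a single integer >= ", min))
    }
  }
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      fail(field, "must be a single positive number")
    }
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
      fail(field, "probabilities must lie in [0, 1]")
    }
  }
  chk_cond_map <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || !all(conds %in% names(v))) {
      fail(field, "must be a named numeric vector covering all six conditions")
    }
  }
  chk_count("n_participants"); chk_count("n_trials_per_condition")
  chk_pos("sample_rate"); chk_pos("rt_base"); chk_pos("it_mean"); chk_pos("it_sd")
  chk_pos("timeout"); chk_pos("initiation_deadline")
  chk_cond_map("rt_offsets"); chk_cond_map("pull_amplitude"); chk_cond_map("pull_prob")
  chk_prob("pull_amplitude"); chk_prob("pull_prob"); chk_prob("error_prob")
  chk_prob("omission_prob"); chk_prob("pull_decay"); chk_prob("pe_pull_amplitude")
  chk_prob("pe_pull_decay")
  chk_pos("pursuit_gain"); chk_pos("velocity_skew")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (!is.numeric(cfg$participant_sd_rt) || cfg$participant_sd_rt < 0) {
    fail("participant_sd_rt", "must be >= 0")
  }
  if (!is.numeric(cfg$participant_sd_pull) || cfg$participant_sd_pull < 0) {
    fail("participant_sd_pull", "must be >= 0")
  }
  if (!is.numeric(cfg$rt_cv) || cfg$rt_cv < 0) fail("rt_cv", "must be >= 0")
  if (cfg$rt_base + min(cfg$rt_offsets[conds]) <= 0) {
    fail("rt_offsets", "rt_base plus the smallest offset must be positive")
  }
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))) {
    fail("seed", "must be a single integer or NULL")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_participants, " participants x 6 conditions x ",
      x$n_trials_per_condition, " trials, ", x$sample_rate, " Hz\n", sep = "")
  cat("  rt_base ", x$rt_base, " ms; offsets: ",
      paste(names(x$rt_offsets), x$rt_offsets, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Ground-truth Stroop components implied by a simulation configuration
#'
#' Applies the eight component contrasts to the configured per-condition mean
#' response times (`rt_base + rt_offsets`). Because the estimated components
#' are the same contrasts applied to estimated marginal means, the ground
#' truth satisfies the identical additivity identities.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with `component` and `true_ms`.
#' @export
#' @examples
#' ground_truth_components(sim_config(n_participants = 2))
ground_truth_components <- function(config) {
  validate_sim_config(config)
  means <- config$rt_base + config$rt_offsets[stroop_conditions()]
  out <- components_from_means(means)
  dplyr::rename(out, true_ms = "estimate")
}
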