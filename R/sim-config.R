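#' Simulation configuration
#'
#' Builds and validates the configuration object for the synthetic
#' two-channel photometry + ladder-behavior generator. Defaults emulate a
#' three-session conditioning experiment of 72 trials per session with a
#' 250-ms CS--US interstimulus interval and GCaMP6f-like transient kinetics.
#'
#' Fluorescence amplitudes (`cs_response_amplitude`,
#' `locomotion_response_amplitude`, `air_response_amplitude`,
#' `artifact_amplitude`, `noise_sd`) are fractional modulations of the
#' bleach-scaled baseline, i.e. they live on the dF/F scale.
#'
#' @param sample_rate_hz Acquisition rate in Hz.
#' @param n_sessions Number of learning sessions.
#' @param n_trials_per_session Trials per session.
#' @param trial_type_fractions Named numeric vector over
#'   `c("unperturbed", "cs_only", "us_only", "paired")`, summing to 1.
#' @param isi_s CS-to-US interstimulus interval in seconds.
#' @param transient_rise_s,transient_decay_s GCaMP kernel time constants (s).
#' @param cs_response_amplitude Peak fractional fluorescence response to the
#'   conditioned stimulus (cohort-dependent; overridden by [cohort_spec()]).
#' @param locomotion_response_amplitude Mean amplitude of locomotion-locked
#'   transients emitted while the animal traverses the ladder.
#' @param air_response_amplitude Amplitude of the response to the pretrial
#'   air cue (cohort-independent).
#' @param session_scale Per-session multiplier on the CS response amplitude
#'   (length `n_sessions` or scalar); the default rises across sessions,
#'   mirroring learning-related growth of the CS response.
#' @param bleach_tau_s,bleach_fraction Single-exponential photobleaching
#'   time constant (s) and asymptotic fractional loss in `[0, 1)`.
#' @param noise_sd SD of white measurement noise (fractional units).
#' @param artifact_rate_hz Rate of brief shared motion artifacts (Hz).
#' @param artifact_amplitude,artifact_duration_s Artifact size (fractional)
#'   and duration (s); artifacts hit both channels identically.
#' @param locomotion_event_rate_hz Rate of locomotion transients within trials.
#' @param baseline_signal,baseline_control Baseline fluorescence of the
#'   GCaMP and isosbestic channels (arbitrary units).
#' @param n_pre_steps,n_post_steps Number of steps before and after the
#'   perturbation point used to build trial durations.
#' @param pre_step_mean_ms,pre_step_sd_ms Pre-perturbation step-time
#'   distribution (cohort-independent).
#' @param penalty_ms Session-1 post-perturbation step-time penalty (ms).
#' @param coupling Strength of the within-trial link between the drawn CS
#'   response amplitude and the post-perturbation penalty (larger CS
#'   responses shrink the penalty).
#' @param iti_s Mean goal-box interval between trials (s).
#' @param reaction_mean_s,reaction_sd_s Air-cue-to-trial-start latency;
#'   negative draws model departures before the cue.
#' @param rung_spacing_m Distance advanced per step, used to derive velocity.
#' @param seed Integer master seed.
#'
#' @return A list of class `fp_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(sample_rate_hz = 100, seed = 7)
#' cfg$isi_s
sim_config <- function(sample_rate_hz = 1000,
                       n_sessions = 3,
                       n_trials_per_session = 72,
                       trial_type_fractions = c(unperturbed = 0.40,
                                                cs_only = 0.175,
                                                us_only = 0.175,
                                                paired = 0.25),
                       isi_s = 0.25,
                       transient_rise_s = 0.05,
                       transient_decay_s = 0.4,
                       cs_response_amplitude = 1.0,
                       locomotion_response_amplitude = 0.3,
                       air_response_amplitude = 0.5,
                       session_scale = NULL,
                       bleach_tau_s = 500,
                       bleach_fraction = 0.3,
                       noise_sd = 0.3,
                       artifact_rate_hz = 0.02,
                       artifact_amplitude = 3.0,
                       artifact_duration_s = 0.05,
                       locomotion_event_rate_hz = 2,
                       baseline_signal = 100,
                       baseline_control = 80,
                       n_pre_steps = 6,
                       n_post_steps = 8,
                       pre_step_mean_ms = 250,
                       pre_step_sd_ms = 30,
                       penalty_ms = 150,
                       coupling = 0.5,
                       iti_s = 2,
                       reaction_mean_s = 0.5,
                       reaction_sd_s = 0.28,
                       rung_spacing_m = 0.03,
                       seed = 1L) {
  cfg <- list(
    sample_rate_hz = sample_rate_hz,
    n_sessions = as.integer(n_sessions),
    n_trials_per_session = as.integer(n_trials_per_session),
    trial_type_fractions = trial_type_fractions,
    isi_s = isi_s,
    transient_rise_s = transient_rise_s,
    transient_decay_s = transient_decay_s,
    cs_response_amplitude = cs_response_amplitude,
    locomotion_response_amplitude = locomotion_response_amplitude,
    air_response_amplitude = air_response_amplitude,
    session_scale = session_scale %||% default_session_scale(n_sessions),
    bleach_tau_s = bleach_tau_s,
    bleach_fraction = bleach_fraction,
    noise_sd = noise_sd,
    artifact_rate_hz = artifact_rate_hz,
    artifact_amplitude = artifact_amplitude,
    artifact_duration_s = artifact_duration_s,
    locomotion_event_rate_hz = locomotion_event_rate_hz,
    baseline_signal = baseline_signal,
    baseline_control = baseline_control,
    n_pre_steps = as.integer(n_pre_steps),
    n_post_steps = as.integer(n_post_steps),
    pre_step_mean_ms = pre_step_mean_ms,
    pre_step_sd_ms = pre_step_sd_ms,
    penalty_ms = penalty_ms,
    coupling = coupling,
    iti_s = iti_s,
    reaction_mean_s = reaction_mean_s,
    reaction_sd_s = reaction_sd_s,
    rung_spacing_m = rung_spacing_m,
    seed = as.integer(seed)
  )
  class(cfg) <- "fp_sim_config"
  validate_sim_config(cfg)
}

# learning-related growth of the CS response across sessions
default_session_scale <- function(n_sessions) {
  if (n_sessions == 1L) return(1)
  seq(0.6, 1, length.out = n_sessions)
}

trial_types <- c("unperturbed", "cs_only", "us_only", "paired")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "fp_sim_config"))
  pos <- c("sample_rate_hz", "isi_s", "transient_rise_s", "transient_decay_s",
           "bleach_tau_s", "baseline_signal", "baseline_control",
           "pre_step_mean_ms", "iti_s", "rung_spacing_m")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      abort(sprintf("`%s` must be a single strictly positive number.", nm))
    }
  }
  nonneg <- c("cs_response_amplitude", "locomotion_response_amplitude",
              "air_response_amplitude", "noise_sd", "artifact_rate_hz",
              "artifact_amplitude", "penalty_ms", "coupling",
              "locomotion_event_rate_hz", "pre_step_sd_ms")
  for (nm in nonneg) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", nm))
    }
  }
  if (cfg$n_sessions < 1L || cfg$n_trials_per_session < 1L) {
    abort("`n_sessions` and `n_trials_per_session` must be >= 1.")
  }
  if (cfg$bleach_fraction < 0 || cfg$bleach_fraction >= 1) {
    abort("`bleach_fraction` must lie in [0, 1).")
  }
  check_fractions(cfg$trial_type_fractions)
  if (length(cfg$session_scale) == 1L) {
    cfg$session_scale <- rep(cfg$session_scale, cfg$n_sessions)
  }
  if (length(cfg$session_scale) != cfg$n_sessions || any(cfg$session_scale < 0)) {
    abort("`session_scale` must be non-negative, length 1 or `n_sessions`.")
  }
  cfg
}

check_fractions <- function(fractions) {
  if (is.null(names(fractions)) || !all(names(fractions) %in% trial_types)) {
    abort(sprintf("trial-type fractions must be named from: %s",
                  paste(trial_types, collapse = ", ")))
  }
  if (any(fractions < 0) || any(fractions > 1)) {
    abort("trial-type fractions must lie in [0, 1].")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort(sprintf("trial-type fractions must sum to 1 (got %.12f).",
                  sum(fractions)))
  }
  invisible(fractions)
}

#' Cohort specification
#'
#' Describes one simulated cohort: its CS--US Purkinje-cell responsiveness
#' and its post-perturbation learning rate. A "responsive" cohort emulates
#' the uninjured phenotype (strong CS responses, fast step-time adaptation);
#' an "attenuated" cohort emulates the injured phenotype (weak CS responses,
#' slow adaptation).
#'
#' @param label `"responsive"` or `"attenuated"`.
#' @param n_mice Number of mice in the cohort.
#' @param cs_response_amplitude Cohort CS response amplitude (fractional
#'   dF/F); defaults to 1.0 for responsive, 0.1 for attenuated.
#' @param learning_rate Exponential decay rate (per session) of the
#'   post-perturbation step-time penalty; defaults to 0.8 for responsive,
#'   0.1 for attenuated.
#' @param amplitude_multipliers Optional vector of per-mouse amplitude
#'   multipliers (length `n_mice`, strictly positive). When `NULL`, they are
#'   drawn log-normally with coefficient of variation `amplitude_cv` from
#'   the cohort sub-seed.
#' @param amplitude_cv Coefficient of variation of per-mouse multipliers.
#'
#' @return A list of class `fp_cohort_spec`.
#' @export
#' @examples
#' cohort_spec("responsive", n_mice = 3)
cohort_spec <- function(label = c("responsive", "attenuated"),
                        n_mice = 3L,
                        cs_response_amplitude = NULL,
                        learning_rate = NULL,
                        amplitude_multipliers = NULL,
                        amplitude_cv = 0.1) {
  label <- match.arg(label)
  defaults <- list(
    responsive = list(amp = 1.0, rate = 0.8),
    attenuated = list(amp = 0.1, rate = 0.1)
  )[[label]]
  n_mice <- as.integer(n_mice)
  if (n_mice < 1L) abort("`n_mice` must be >= 1.")
  amp <- cs_response_amplitude %||% defaults$amp
  if (amp < 0) abort("`cs_response_amplitude` must be >= 0.")
  rate <- learning_rate %||% defaults$rate
  if (rate < 0) abort("`learning_rate` must be >= 0.")
  if (!is.null(amplitude_multipliers)) {
    if (length(amplitude_multipliers) != n_mice ||
        any(amplitude_multipliers <= 0)) {
      abort("`amplitude_multipliers` must be strictly positive, length `n_mice`.")
    }
  }
  structure(list(label = label,
                 n_mice = n_mice,
                 cs_response_amplitude = amp,
                 learning_rate = rate,
                 amplitude_multipliers = amplitude_multipliers,
                 amplitude_cv = amplitude_cv),
            class = "fp_cohort_spec")
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Sub-seeds for per-mouse/per-session streams are derived by a documented
#' counter scheme so that partial re-runs reproduce the same draws: the
#' master seed and a small vector of indices are folded through fixed
#' multipliers modulo `2^31 - 1`.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices (e.g. cohort, mouse, session counters).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- as.numeric(seed) %% m
  mult <- c(48271, 69621, 16807, 40692, 10007, 104729)
  for (i in seq_along(idx)) {
    k <- mult[((i - 1L) %% length(mult)) + 1L]
    s <- (s * 31 + (as.numeric(idx[i]) + 1) * k) %% m
  }
  as.integer(s %% (m - 2) + 1)
}
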