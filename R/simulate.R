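# Synthetic two-channel photometry + ladder-behavior generator.
#
# The generator produces, per mouse and session: a RawRecording (GCaMP signal
# channel + 410-nm isosbestic control channel on a uniform time grid), an
# event stream (air_cue, trial_start, cs_onset, us_onset, trial_end) and a
# per-trial behavior table. Fluorescence is modeled as
#   signal  = B_s * bleach(t) * (1 + activity + artifact + noise)
#   control = B_c * bleach(t) * (1 + artifact + noise')
# so CS-, air- and locomotion-locked transients live only in the signal
# channel while bleaching and brief motion artifacts are shared, which is
# exactly the structure the isosbestic correction assumes.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Build a seeded trial-type schedule
#'
#' Allocates trial types by largest-remainder apportionment (each type gets
#' `floor(n * fraction)` trials; leftover slots go to the largest fractional
#' remainders, ties resolved in type order unperturbed, cs_only, us_only,
#' paired) and returns them in a seeded random order.
#'
#' @param n_trials Number of trials (>= 1).
#' @param fractions Named fractions over the four trial types, summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return Character vector of length `n_trials` with values among
#'   `"unperturbed"`, `"cs_only"`, `"us_only"`, `"paired"`.
#' @export
#' @examples
#' table(make_trial_schedule(72, c(paired = 1), seed = 1))
make_trial_schedule <- function(n_trials, fractions, seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) abort("`n_trials` must be >= 1.")
  fr <- setNames(numeric(4), trial_types)
  fr[names(fractions)] <- fractions
  check_fractions(fr)
  counts <- largest_remainder(n_trials, fr)
  pool <- rep(names(counts), counts)
  with_seed(seed, sample(pool, length(pool)))
}

largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  counts <- floor(exact)
  leftover <- n - sum(counts)
  if (leftover > 0) {
    rem <- exact - counts
    # ties broken by position, matching order of `fractions`
    take <- order(rem, decreasing = TRUE)[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts) |> setNames(names(fractions))
}

#' Simulate per-trial ladder behavior
#'
#' Draws step times for one session of one mouse. Pre-perturbation step
#' times come from a cohort-independent truncated normal; trials carrying
#' the obstacle (paired, us_only) add a post-perturbation penalty that
#' decays across sessions at the cohort's `learning_rate` and, within a
#' trial, shrinks with the drawn CS response amplitude (`coupling`), so
#' stronger anticipatory Purkinje responses co-occur with better-adapted
#' steps. Trial duration and velocity are derived from the summed step
#' times.
#'
#' @param schedule Character vector of trial types (from
#'   [make_trial_schedule()]).
#' @param cohort An [cohort_spec()] object.
#' @param session_index Session number in `1..n_sessions`.
#' @param config An [sim_config()] object.
#' @param seed Integer seed.
#' @param mouse_multiplier Per-mouse CS amplitude multiplier.
#' @return Tibble with one row per trial: `type`, `cs_amp`, `pre_step_ms`,
#'   `post_step_ms`, `duration_s`, `velocity`.
#' @export
simulate_behavior <- function(schedule, cohort, session_index, config,
                              seed = config$seed, mouse_multiplier = 1) {
  stopifnot(inherits(cohort, "fp_cohort_spec"))
  config <- validate_sim_config(config)
  if (session_index < 1L || session_index > config$n_sessions) {
    abort(sprintf("`session_index` must lie in [1, %d].", config$n_sessions))
  }
  with_seed(seed, {
    n <- length(schedule)
    has_cs <- schedule %in% c("paired", "cs_only")
    has_us <- schedule %in% c("paired", "us_only")
    scale_s <- config$session_scale[session_index]
    cs_amp <- ifelse(
      has_cs,
      cohort$cs_response_amplitude * mouse_multiplier * scale_s *
        exp(rnorm(n, 0, 0.2)),
      0
    )
    penalty <- ifelse(
      has_us,
      config$penalty_ms * exp(-cohort$learning_rate * (session_index - 1)) *
        exp(-config$coupling * cs_amp),
      0
    )
    # per-step draws, floored at 50 ms; trial value is the mean over steps
    kp <- config$n_pre_steps
    kq <- config$n_post_steps
    pre <- rowMeans(matrix(
      pmax(rnorm(n * kp, config$pre_step_mean_ms, config$pre_step_sd_ms), 50),
      nrow = n))
    post <- rowMeans(matrix(
      pmax(rnorm(n * kq, rep(config$pre_step_mean_ms + penalty, kq),
                 config$pre_step_sd_ms), 50),
      nrow = n))
    n_steps <- config$n_pre_steps + config$n_post_steps
    duration <- (config$n_pre_steps * pre + config$n_post_steps * post) / 1000 +
      config$isi_s
    tibble(
      type = schedule,
      cs_amp = cs_amp,
      pre_step_ms = pre,
      post_step_ms = post,
      duration_s = duration,
      velocity = n_steps * config$rung_spacing_m / duration
    )
  })
}

#' Lay out session events on the recording clock
#'
#' Converts a behavior table into an absolute-time event stream and trial
#' table: each trial gets an air cue, a trial start after a (possibly
#' negative) reaction latency, a CS and/or US at the perturbation point, and
#' a trial end; trials are separated by goal-box intervals.
#'
#' @inheritParams simulate_behavior
#' @param behavior Tibble from [simulate_behavior()].
#' @param pad_s Quiet padding before the first cue and after the last trial.
#' @return List with `events` (tibble `timestamp_s`, `event_type`, sorted)
#'   and `trials` (per-trial table with absolute times and
#'   `left_before_cue`).
#' @export
simulate_events <- function(behavior, config, seed = config$seed, pad_s = 3) {
  config <- validate_sim_config(config)
  with_seed(seed, {
    n <- nrow(behavior)
    reaction <- rnorm(n, config$reaction_mean_s, config$reaction_sd_s)
    iti <- config$iti_s + runif(n, 0, 0.5)
    t_air <- numeric(n)
    t_start <- numeric(n)
    clock <- pad_s
    for (i in seq_len(n)) {
      t_air[i] <- clock
      t_start[i] <- t_air[i] + reaction[i]
      clock <- max(t_air[i], t_start[i]) + behavior$duration_s[i] + iti[i]
    }
    pre_phase <- config$n_pre_steps * behavior$pre_step_ms / 1000
    has_cs <- behavior$type %in% c("paired", "cs_only")
    has_us <- behavior$type %in% c("paired", "us_only")
    t_perturb <- t_start + pre_phase + config$isi_s
    t_cs <- ifelse(has_cs, t_perturb - config$isi_s, NA_real_)
    t_us <- ifelse(has_us, t_perturb, NA_real_)
    t_end <- t_start + behavior$duration_s
    trials <- behavior |>
      mutate(
        trial_index = seq_len(n),
        t_air_s = t_air,
        t_start_s = t_start,
        t_cs_s = t_cs,
        t_us_s = t_us,
        t_end_s = t_end,
        left_before_cue = t_start < t_air,
        .before = 1
      ) |>
      relocate("trial_index", "type")
    ev <- tibble(
      timestamp_s = c(t_air, t_start, t_cs[has_cs], t_us[has_us], t_end),
      event_type = c(rep("air_cue", n), rep("trial_start", n),
                     rep("cs_onset", sum(has_cs)),
                     rep("us_onset", sum(has_us)),
                     rep("trial_end", n))
    ) |>
      arrange(.data$timestamp_s)
    list(events = ev, trials = trials)
  })
}

# double-exponential GCaMP-like kernel, peak-normalized to 1
gcamp_kernel <- function(rise_s, decay_s, sample_rate_hz) {
  tt <- seq(0, rise_s + 5 * decay_s, by = 1 / sample_rate_hz)
  k <- (1 - exp(-tt / rise_s)) * exp(-tt / decay_s)
  k / max(k)
}

#' Simulate a two-channel photometry recording
#'
#' Builds the GCaMP signal channel and the isosbestic control channel for
#' one session. The signal channel carries CS-locked transients (amplitude
#' per trial from the behavior table), air-cue responses and
#' locomotion-locked transients during trials, all convolved with a
#' double-exponential GCaMP kernel; both channels share a single-exponential
#' bleach and brief half-cosine motion artifacts, plus independent white
#' noise. The control channel has no stimulus- or locomotion-locked
#' component.
#'
#' @param trials Trial table from [simulate_events()] (needs `t_start_s`,
#'   `t_end_s`, `t_cs_s`, `t_air_s`, `cs_amp`).
#' @param config An [sim_config()] object.
#' @param seed Integer seed.
#' @param pad_s Padding after the last trial end (s).
#' @return An `fp_recording` tibble (`time_s`, `signal`, `control`) with a
#'   `sample_rate_hz` attribute; both channels strictly positive.
#' @export
simulate_trace_pair <- function(trials, config, seed = config$seed, pad_s = 3) {
  config <- validate_sim_config(config)
  fs <- config$sample_rate_hz
  t_total <- max(trials$t_end_s) + pad_s
  n <- floor(t_total * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  at_idx <- function(t) pmin(pmax(round(t * fs) + 1L, 1L), n)
  with_seed(seed, {
    impulses <- numeric(n)
    cs_rows <- which(!is.na(trials$t_cs_s) & trials$cs_amp > 0)
    if (length(cs_rows)) {
      ii <- at_idx(trials$t_cs_s[cs_rows])
      impulses[ii] <- impulses[ii] + trials$cs_amp[cs_rows]
    }
    if (config$air_response_amplitude > 0) {
      ii <- at_idx(trials$t_air_s)
      impulses[ii] <- impulses[ii] + config$air_response_amplitude
    }
    if (config$locomotion_response_amplitude > 0 &&
        config$locomotion_event_rate_hz > 0) {
      for (i in seq_len(nrow(trials))) {
        dur <- trials$t_end_s[i] - trials$t_start_s[i]
        k <- rpois(1, config$locomotion_event_rate_hz * dur)
        if (k > 0) {
          tl <- trials$t_start_s[i] + runif(k, 0, dur)
          ii <- at_idx(tl)
          amps <- config$locomotion_response_amplitude * exp(rnorm(k, 0, 0.3))
          for (j in seq_len(k)) impulses[ii[j]] <- impulses[ii[j]] + amps[j]
        }
      }
    }
    kern <- gcamp_kernel(config$transient_rise_s, config$transient_decay_s, fs)
    activity <- if (any(impulses != 0)) {
      stats::convolve(impulses, rev(kern), type = "open")[seq_len(n)]
    } else {
      numeric(n)
    }
    artifact <- numeric(n)
    n_art <- rpois(1, config$artifact_rate_hz * t_total)
    if (n_art > 0 && config$artifact_amplitude > 0) {
      t_art <- runif(n_art, 0, t_total)
      sgn <- sample(c(-1, 1), n_art, replace = TRUE)
      w <- max(3L, round(config$artifact_duration_s * fs))
      pulse <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
      for (j in seq_len(n_art)) {
        i0 <- at_idx(t_art[j])
        span <- i0:min(i0 + w - 1L, n)
        artifact[span] <- artifact[span] +
          sgn[j] * config$artifact_amplitude * pulse[seq_along(span)]
      }
    }
    bleach <- (1 - config$bleach_fraction) +
      config$bleach_fraction * exp(-tt / config$bleach_tau_s)
    eps_s <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
    eps_c <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
    sig <- config$baseline_signal * bleach * (1 + activity + artifact + eps_s)
    ctl <- config$baseline_control * bleach * (1 + artifact + eps_c)
    new_recording(
      time_s = tt,
      signal = pmax(sig, 1e-6 * config$baseline_signal),
      control = pmax(ctl, 1e-6 * config$baseline_control),
      sample_rate_hz = fs
    )
  })
}

#' Construct a raw two-channel recording
#'
#' @param time_s Uniformly spaced time vector (s).
#' @param signal,control Fluorescence channels (arbitrary units).
#' @param sample_rate_hz Sample rate (Hz), consistent with `time_s`.
#' @return An `fp_recording` tibble.
#' @export
new_recording <- function(time_s, signal, control, sample_rate_hz) {
  if (length(time_s) < 2L || length(signal) != length(time_s) ||
      length(control) != length(time_s)) {
    abort("`time_s`, `signal`, `control` must have equal length >= 2.")
  }
  dt <- diff(time_s)
  if (any(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-12))) {
    abort("`time_s` must be uniformly spaced.")
  }
  if (abs(dt[1] - 1 / sample_rate_hz) > 1e-6 * dt[1]) {
    abort("`sample_rate_hz` is inconsistent with the spacing of `time_s`.")
  }
  out <- tibble(time_s = time_s, signal = signal, control = control)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("fp_recording", class(out))
  out
}

#' Sample rate of a recording or trace
#' @param x An `fp_recording` or `fp_trace`.
#' @return Sample rate in Hz.
#' @export
sample_rate <- function(x) {
  fs <- attr(x, "sample_rate_hz")
  if (is.null(fs)) abort("object carries no `sample_rate_hz` attribute.")
  fs
}

#' Simulate one mouse-session
#'
#' Composes schedule, behavior, event layout and trace generation for a
#' single session, with all randomness derived from one seed.
#'
#' @inheritParams simulate_behavior
#' @return List with `recording`, `events`, `trials` (the trial table with
#'   session and absolute times).
#' @export
simulate_session <- function(cohort, session_index, config,
                             seed = config$seed, mouse_multiplier = 1) {
  schedule <- make_trial_schedule(config$n_trials_per_session,
                                  config$trial_type_fractions,
                                  seed = derive_seed(seed, 1L))
  behavior <- simulate_behavior(schedule, cohort, session_index, config,
                                seed = derive_seed(seed, 2L),
                                mouse_multiplier = mouse_multiplier)
  laid <- simulate_events(behavior, config, seed = derive_seed(seed, 3L))
  rec <- simulate_trace_pair(laid$trials, config, seed = derive_seed(seed, 4L))
  trials <- laid$trials |> mutate(session = session_index, .after = "trial_index")
  list(recording = rec, events = laid$events, trials = trials)
}

#' Simulate a complete multi-cohort experiment
#'
#' Generates, per cohort, mouse and session, a full recording + event stream
#' + trial table. Per-mouse amplitude multipliers and per-session seeds are
#' derived deterministically from the master seed by [derive_seed()], so any
#' subset of the experiment reproduces exactly.
#'
#' @param cohorts List of [cohort_spec()] objects (>= 1).
#' @param config An [sim_config()] object; `config$seed` is the master seed.
#' @return A nested tibble with columns `cohort`, `mouse`, `session`,
#'   and list-columns `recording`, `events`, `trials`; the config is
#'   attached as attribute `config`.
#' @export
#' @examples
#' cfg <- sim_config(sample_rate_hz = 50, n_trials_per_session = 4,
#'                   n_sessions = 1, seed = 2)
#' ds <- simulate_cohort(list(cohort_spec("responsive", n_mice = 1)), cfg)
#' ds$trials[[1]]
simulate_cohort <- function(cohorts, config) {
  if (inherits(cohorts, "fp_cohort_spec")) cohorts <- list(cohorts)
  if (!length(cohorts)) abort("at least one cohort is required.")
  config <- validate_sim_config(config)
  rows <- list()
  for (ci in seq_along(cohorts)) {
    ch <- cohorts[[ci]]
    mult <- ch$amplitude_multipliers %||% with_seed(
      derive_seed(config$seed, ci, 0L),
      exp(rnorm(ch$n_mice, 0, ch$amplitude_cv))
    )
    for (mi in seq_len(ch$n_mice)) {
      for (si in seq_len(config$n_sessions)) {
        sess <- simulate_session(
          ch, si, config,
          seed = derive_seed(config$seed, ci, mi, si),
          mouse_multiplier = mult[mi]
        )
        rows[[length(rows) + 1L]] <- tibble(
          cohort = ch$label,
          mouse = sprintf("%s_m%d", ch$label, mi),
          session = si,
          recording = list(sess$recording),
          events = list(sess$events),
          trials = list(sess$trials)
        )
      }
    }
  }
  out <- list_rbind(rows)
  attr(out, "config") <- config
  out
}
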