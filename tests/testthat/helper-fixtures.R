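# Shared fixtures: small, fast configurations and hand-built objects.

# compact experiment for unit tests: low rate, few trials
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(
      sample_rate_hz = 50,
      n_sessions = 2,
      n_trials_per_session = 6,
      trial_type_fractions = c(paired = 0.5, cs_only = 0.5 / 3,
                               us_only = 0.5 / 3, unperturbed = 0.5 / 3),
      iti_s = 1,
      seed = seed
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# noiseless, transient-free flat recording
flat_recording <- function(n = 500, fs = 100, signal = 100, control = 80) {
  tt <- (seq_len(n) - 1) / fs
  new_recording(tt, rep(signal, n), rep(control, n), fs)
}

# build an fp_window directly on an exact grid: z = f(rel_time)
make_window <- function(f, fs = 1000, pre_s = 0.5, post_s = 1.5) {
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  rel <- (seq(-n_pre, n_post - 1)) / fs
  w <- tibble::tibble(rel_time_s = rel, z = f(rel))
  attr(w, "sample_rate_hz") <- fs
  attr(w, "t0_kind") <- "cs_onset"
  class(w) <- c("fp_window", class(w))
  w
}

# event stream tibble from vectors
ev <- function(timestamp_s, event_type) {
  tibble::tibble(timestamp_s = timestamp_s, event_type = event_type)
}
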