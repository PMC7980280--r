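# Segmentation, classification, window extraction.

test_that("segmentation pairs starts with ends and reports orphans", {
  e <- ev(c(10, 25, 40, 58), c("trial_start", "trial_end", "trial_start",
                               "trial_end"))
  iv <- segment_trials(e)
  expect_equal(iv$t_start_s, c(10, 40))
  expect_equal(iv$t_end_s, c(25, 58))
  expect_equal(nrow(attr(iv, "orphans")), 0)

  empty <- ev(numeric(0), character(0))
  expect_equal(nrow(segment_trials(empty)), 0)

  lone <- ev(10, "trial_start")
  iv <- segment_trials(lone)
  expect_equal(nrow(iv), 0)
  expect_equal(attr(iv, "orphans")$event_type, "trial_start")

  # start-start-end: the first start is orphaned, not bridged
  e3 <- ev(c(1, 2, 3), c("trial_start", "trial_start", "trial_end"))
  iv3 <- segment_trials(e3)
  expect_equal(iv3$t_start_s, 2)
  expect_equal(attr(iv3, "orphans")$timestamp_s, 1)
})

test_that("trial classification follows the CS/US membership rule", {
  base <- function(extra_t, extra_k) {
    ev(c(0, extra_t, 10), c("trial_start", extra_k, "trial_end"))
  }
  expect_equal(classify_trial(base(c(2, 2.25), c("cs_onset", "us_onset")),
                              0, 10)$type, "paired")
  expect_equal(classify_trial(base(2, "cs_onset"), 0, 10)$type, "cs_only")
  expect_equal(classify_trial(base(2, "us_onset"), 0, 10)$type, "us_only")
  expect_equal(classify_trial(base(numeric(0), character(0)), 0, 10)$type,
               "unperturbed")
  # first occurrence is canonical
  cl <- classify_trial(base(c(2, 3), c("cs_onset", "cs_onset")), 0, 10)
  expect_equal(cl$t_cs_s, 2)
})

test_that("annotate_trials matches a brute-force oracle on random schedules", {
  set.seed(11)
  for (rep in 1:50) {
    n_tr <- sample(1:8, 1)
    starts <- sort(runif(n_tr, 0, 100))
    ends <- starts + runif(n_tr, 0.5, 2)
    keep_end <- runif(n_tr) > 0.15 # some orphans
    stamps <- c(starts, ends[keep_end])
    kinds <- c(rep("trial_start", n_tr), rep("trial_end", sum(keep_end)))
    extras_t <- runif(2 * n_tr, 0, 105)
    extras_k <- sample(c("cs_onset", "us_onset", "air_cue"), 2 * n_tr,
                       replace = TRUE)
    events <- ev(c(stamps, extras_t), c(kinds, extras_k)) |>
      dplyr::arrange(timestamp_s)
    got <- annotate_trials(events)
    # oracle: a start matches the next end before any further start
    exp_iv <- list()
    open <- NA
    bm <- events[events$event_type %in% c("trial_start", "trial_end"), ]
    for (i in seq_len(nrow(bm))) {
      if (bm$event_type[i] == "trial_start") open <- bm$timestamp_s[i]
      else if (!is.na(open)) {
        exp_iv[[length(exp_iv) + 1]] <- c(open, bm$timestamp_s[i])
        open <- NA
      }
    }
    expect_equal(nrow(got), length(exp_iv))
    for (i in seq_along(exp_iv)) {
      a <- exp_iv[[i]][1]; b <- exp_iv[[i]][2]
      has_cs <- any(extras_k == "cs_onset" & extras_t >= a & extras_t <= b)
      has_us <- any(extras_k == "us_onset" & extras_t >= a & extras_t <= b)
      want <- if (has_cs && has_us) "paired" else if (has_cs) "cs_only"
      else if (has_us) "us_only" else "unperturbed"
      expect_equal(got$type[i], want)
    }
  }
})

test_that("segmentation is idempotent under re-annotation", {
  cfg <- tiny_config(seed = 13)
  sess <- simulate_session(cohort_spec("responsive", 1), 1, cfg)
  a <- annotate_trials(sess$events)
  b <- annotate_trials(sess$events)
  expect_identical(a, b)
  expect_equal(a$type, sess$trials$type)
  expect_equal(a$t_start_s, sess$trials$t_start_s, tolerance = 1e-9)
})

test_that("window extraction is sample-exact", {
  fs <- 100
  n <- 1000
  trace <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, dff = 0,
                          z = rep(0, n))
  attr(trace, "sample_rate_hz") <- fs
  class(trace) <- c("fp_trace", class(trace))
  w <- extract_window(trace, 5)
  expect_equal(nrow(w), round(2 * fs))
  expect_true(all(w$z == 0))
  expect_equal(w$rel_time_s[1], -0.5)
  expect_equal(w$rel_time_s[nrow(w)], 1.5 - 1 / fs)
  expect_equal(sum(w$rel_time_s == 0), 1)

  expect_error(extract_window(trace, 0.2), "bounds")
  expect_error(extract_window(trace, 9.9), "bounds")
})

test_that("an injected transient peaks at its latency within one sample", {
  fs <- 250
  n <- 5000
  z <- numeric(n)
  t0 <- 10
  latency <- 0.12
  z[round((t0 + latency) * fs) + 1] <- 5
  trace <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, dff = z, z = z)
  attr(trace, "sample_rate_hz") <- fs
  class(trace) <- c("fp_trace", class(trace))
  w <- extract_window(trace, t0)
  expect_lt(abs(w$rel_time_s[which.max(w$z)] - latency), 1 / fs + 1e-12)
})

test_that("US onset lands at rel_time 0.25 within one sample on paired trials", {
  cfg <- tiny_config(n_trials_per_session = 6, noise_sd = 0,
                     locomotion_response_amplitude = 0,
                     air_response_amplitude = 0, artifact_rate_hz = 0,
                     trial_type_fractions = c(paired = 1), seed = 14)
  sess <- simulate_session(cohort_spec("responsive", 1), 1, cfg)
  fs <- sample_rate(sess$recording)
  tr <- suppressWarnings(process_recording(sess$recording))
  der <- annotate_trials(sess$events)
  for (i in seq_len(nrow(der))) {
    w <- extract_window(tr, der$t_cs_s[i])
    i_us <- which.min(abs(w$rel_time_s - 0.25))
    # the sample at rel 0.25 is the sample nearest the recorded US onset
    t_abs <- der$t_cs_s[i] + w$rel_time_s[i_us]
    expect_lt(abs(t_abs - der$t_us_s[i]), 1 / fs + 1e-12)
  }
})

test_that("air-puff windows are extracted per cue and skip near-boundary cues", {
  fs <- 50
  n <- 5000
  z <- rnorm(n)
  trace <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, dff = z, z = z)
  attr(trace, "sample_rate_hz") <- fs
  class(trace) <- c("fp_trace", class(trace))
  cues <- c(0.1, seq(5, 90, by = 5))
  events <- ev(cues, rep("air_cue", length(cues)))
  expect_warning(got <- extract_airpuff_windows(trace, events),
                 "out of bounds")
  expect_equal(nrow(got), length(cues) - 1)
  expect_error(extract_airpuff_windows(trace, ev(1, "trial_start")),
               "air_cue")
})

test_that("both cohorts respond to the air cue", {
  post_cue_mean <- function(label) {
    cfg <- tiny_config(n_trials_per_session = 20, noise_sd = 0.1,
                       locomotion_response_amplitude = 0,
                       trial_type_fractions = c(paired = 1), seed = 15)
    sess <- simulate_session(cohort_spec(label, 1), 1, cfg)
    tr <- suppressWarnings(process_recording(sess$recording))
    wins <- extract_airpuff_windows(tr, sess$events)
    pooled <- pool_windows(wins)
    mean(pooled$mean_z[pooled$rel_time_s >= 0 & pooled$rel_time_s < 0.5])
  }
  expect_gt(post_cue_mean("responsive"), 0.2)
  expect_gt(post_cue_mean("attenuated"), 0.2)
})
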