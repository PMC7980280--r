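# Generator: schedules, trace structure, behavior, cohort assembly.

test_that("trial schedules follow largest-remainder apportionment", {
  s <- make_trial_schedule(72, c(paired = 1), seed = 1)
  expect_length(s, 72)
  expect_true(all(s == "paired"))

  s <- make_trial_schedule(4, c(paired = 0.5, cs_only = 0.5), seed = 3)
  expect_equal(as.integer(sort(table(s))), c(2L, 2L))

  # floor(3.3, 3.3, 3.4, 0) = (3, 3, 3, 0); the one leftover slot goes to
  # the 0.34 type (largest remainder), giving (3, 3, 4, 0)
  s <- make_trial_schedule(10, c(unperturbed = 0.33, cs_only = 0.33,
                                 us_only = 0.34, paired = 0), seed = 5)
  counts <- table(factor(s, levels = c("unperturbed", "cs_only", "us_only",
                                       "paired")))
  expect_equal(unname(c(counts)), c(3L, 3L, 4L, 0L))

  # conservation property across random fraction draws
  set.seed(42)
  for (i in 1:25) {
    fr <- runif(4)
    fr <- fr / sum(fr)
    names(fr) <- c("unperturbed", "cs_only", "us_only", "paired")
    n <- sample(5:200, 1)
    s <- make_trial_schedule(n, fr, seed = i)
    exact <- n * fr
    base <- floor(exact)
    leftover <- n - sum(base)
    expected <- base
    if (leftover > 0) {
      take <- order(exact - base, decreasing = TRUE)[seq_len(leftover)]
      expected[take] <- expected[take] + 1
    }
    got <- table(factor(s, levels = names(fr)))
    expect_equal(unname(c(got)), unname(as.integer(expected)))
  }

  expect_error(make_trial_schedule(10, c(paired = 0.6)), "sum to 1")
})

test_that("schedule order is a seeded shuffle", {
  fr <- c(paired = 0.5, cs_only = 0.5)
  expect_identical(make_trial_schedule(20, fr, seed = 7),
                   make_trial_schedule(20, fr, seed = 7))
  expect_false(identical(make_trial_schedule(20, fr, seed = 7),
                         make_trial_schedule(20, fr, seed = 8)))
})

test_that("trace pair is constant when all modulation sources are off", {
  cfg <- tiny_config(cs_response_amplitude = 0,
                     locomotion_response_amplitude = 0,
                     air_response_amplitude = 0,
                     noise_sd = 0, artifact_rate_hz = 0, bleach_fraction = 0)
  sess <- simulate_session(cohort_spec("responsive", 1,
                                       cs_response_amplitude = 0), 1, cfg)
  rec <- sess$recording
  expect_equal(diff(range(rec$signal)), 0)
  expect_equal(diff(range(rec$control)), 0)
  expect_true(all(rec$signal > 0) && all(rec$control > 0))
})

test_that("identical config and seed give identical traces", {
  cfg <- tiny_config(seed = 21)
  a <- simulate_session(cohort_spec("responsive"), 1, cfg, seed = 99)
  b <- simulate_session(cohort_spec("responsive"), 1, cfg, seed = 99)
  expect_identical(a$recording, b$recording)
  expect_identical(a$events, b$events)
  expect_identical(a$trials, b$trials)
})

test_that("CS responses raise signal in CS windows only when amplitude > 0", {
  mean_cs_signal <- function(amp) {
    cfg <- tiny_config(n_trials_per_session = 8, noise_sd = 0.05,
                       artifact_rate_hz = 0, bleach_fraction = 0,
                       locomotion_response_amplitude = 0,
                       air_response_amplitude = 0,
                       trial_type_fractions = c(paired = 1))
    ch <- cohort_spec("responsive", 1, cs_response_amplitude = amp)
    sess <- simulate_session(ch, 1, cfg, seed = 4)
    fs <- sample_rate(sess$recording)
    cs <- sess$trials$t_cs_s
    mean(vapply(cs, function(t0) {
      i0 <- round(t0 * fs) + 1
      mean(sess$recording$signal[i0:(i0 + round(0.25 * fs))])
    }, numeric(1)))
  }
  expect_gt(mean_cs_signal(1), mean_cs_signal(0) + 5)
})

test_that("control channel carries no CS-locked transient", {
  cfg <- sim_config(sample_rate_hz = 50, n_sessions = 1,
                    n_trials_per_session = 72, iti_s = 1,
                    trial_type_fractions = c(paired = 1), seed = 31)
  sess <- simulate_session(cohort_spec("responsive", 1), 1, cfg)
  ctl <- suppressWarnings(correct_bleaching(sess$recording$control,
                                            sess$recording$time_s))
  fs <- sample_rate(sess$recording)
  kern <- ladderfp:::gcamp_kernel(cfg$transient_rise_s,
                                  cfg$transient_decay_s, fs)
  n_k <- length(kern)
  avg <- rowMeans(vapply(sess$trials$t_cs_s, function(t0) {
    i0 <- round(t0 * fs) + 1
    as.numeric(ctl[i0:(i0 + n_k - 1)])
  }, numeric(n_k)))
  expect_lt(abs(cor(avg, kern)), 0.1)
})

test_that("post-perturbation penalty follows learning rate and cohort", {
  cfg <- tiny_config(pre_step_sd_ms = 0, n_sessions = 3,
                     trial_type_fractions = c(us_only = 1))
  sched <- make_trial_schedule(6, c(us_only = 1), seed = 1)
  frozen <- cohort_spec("responsive", 1, learning_rate = 0)
  b1 <- simulate_behavior(sched, frozen, 1, cfg, seed = 2)
  b3 <- simulate_behavior(sched, frozen, 3, cfg, seed = 2)
  # zero learning rate: the penalty is identical across sessions
  expect_equal(b1$post_step_ms - b1$pre_step_ms,
               b3$post_step_ms - b3$pre_step_ms)
  expect_true(all(b1$post_step_ms - b1$pre_step_ms > 0))

  # no penalty: post matches pre distributionally
  cfg0 <- tiny_config(penalty_ms = 0, n_trials_per_session = 40)
  sched40 <- make_trial_schedule(200, c(paired = 1), seed = 1)
  b0 <- simulate_behavior(sched40, cohort_spec("responsive", 1), 1, cfg0,
                          seed = 3)
  expect_lt(abs(mean(b0$post_step_ms) - mean(b0$pre_step_ms)), 10)

  # session 3, large n: responsive adapts faster than attenuated
  cfgL <- tiny_config(n_sessions = 3)
  bR <- simulate_behavior(sched40, cohort_spec("responsive", 1), 3, cfgL,
                          seed = 4)
  bA <- simulate_behavior(sched40, cohort_spec("attenuated", 1), 3, cfgL,
                          seed = 4)
  expect_lt(mean(bR$post_step_ms), mean(bA$post_step_ms))

  # duration and velocity consistent with summed step times
  n_steps <- cfgL$n_pre_steps + cfgL$n_post_steps
  expect_equal(bR$duration_s,
               (cfgL$n_pre_steps * bR$pre_step_ms +
                  cfgL$n_post_steps * bR$post_step_ms) / 1000 + cfgL$isi_s)
  expect_equal(bR$velocity, n_steps * cfgL$rung_spacing_m / bR$duration_s)
})

test_that("cohort datasets have the designed shape and reproduce end-to-end", {
  cfg <- sim_config(sample_rate_hz = 50, n_sessions = 2,
                    n_trials_per_session = 5, iti_s = 1, seed = 17)
  cohorts <- list(cohort_spec("responsive", 2), cohort_spec("attenuated", 2))
  ds <- simulate_cohort(cohorts, cfg)
  expect_equal(nrow(ds), 2 * 2 * 2)
  expect_equal(sum(vapply(ds$trials, nrow, integer(1))), 2 * 2 * 2 * 5)
  ds2 <- simulate_cohort(cohorts, cfg)
  expect_identical(
    serialize(ds, NULL, version = 3),
    serialize(ds2, NULL, version = 3)
  )
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(isi_s = -1), "positive")
  expect_error(sim_config(bleach_fraction = 1), "\\[0, 1\\)")
  expect_error(sim_config(trial_type_fractions = c(paired = 0.5)), "sum to 1")
  expect_error(cohort_spec("responsive", 0), "n_mice")
  expect_error(cohort_spec("responsive", cs_response_amplitude = -1), ">= 0")
})
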