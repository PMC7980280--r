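# Preprocessing: artifact removal, bleach correction, control filtering,
# isosbestic dF/F, z-scoring, full composition.

test_that("artifact removal flags joint deviations only", {
  rec <- flat_recording(2000, 100)
  clean <- remove_artifacts(rec)
  expect_equal(sum(attr(clean, "artifact_mask")), 0)

  set.seed(1)
  n <- 2000
  tt <- (seq_len(n) - 1) / 100
  sig <- 100 + rnorm(n, 0, 1)
  ctl <- 80 + rnorm(n, 0, 1)
  span <- 1000:1004
  sig2 <- sig; ctl2 <- ctl
  sig2[span] <- sig2[span] + 20 * mad(sig - stats::runmed(sig, 101))
  ctl2[span] <- ctl2[span] + 20 * mad(ctl - stats::runmed(ctl, 101))
  rec2 <- new_recording(tt, sig2, ctl2, 100)
  mask <- attr(remove_artifacts(rec2), "artifact_mask")
  expect_true(all(mask[span]))
  expect_lt(sum(mask[-span]), 3)

  # unilateral spike = true transient, preserved
  sig3 <- sig
  sig3[span] <- sig3[span] + 25
  rec3 <- new_recording(tt, sig3, ctl, 100)
  mask3 <- attr(remove_artifacts(rec3), "artifact_mask")
  expect_false(any(mask3[span]))
})

test_that("flagged samples are interpolated", {
  set.seed(2)
  n <- 1000
  tt <- (seq_len(n) - 1) / 100
  sig <- 100 + rnorm(n, 0, 0.5)
  ctl <- 80 + rnorm(n, 0, 0.5)
  sig[500] <- 300; ctl[500] <- 250
  rec <- new_recording(tt, sig, ctl, 100)
  clean <- remove_artifacts(rec)
  expect_true(attr(clean, "artifact_mask")[500])
  expect_lt(abs(clean$signal[500] - 100), 3)
})

test_that("bleach correction recovers tau within 1% on noiseless exponentials", {
  fs <- 100
  tt <- seq(0, 300, by = 1 / fs)
  for (tau in c(60, 150)) {
    ch <- 50 + 40 * exp(-tt / tau)
    out <- correct_bleaching(ch, tt)
    expect_equal(attr(out, "method"), "exponential")
    expect_lt(abs(attr(out, "fit")[["tau"]] - tau) / tau, 0.01)
    expect_lt(max(abs(out - 1)), 1e-3)
  }
})

test_that("bleach correction preserves transient amplitudes within 5%", {
  fs <- 100
  tt <- seq(0, 300, by = 1 / fs)
  tau <- 100
  base <- 60 + 40 * exp(-tt / tau)
  kern <- ladderfp:::gcamp_kernel(0.05, 0.4, fs)
  imp <- numeric(length(tt))
  peaks <- seq(20, 280, by = 10)
  imp[round(peaks * fs) + 1] <- 0.5
  transients <- stats::convolve(imp, rev(kern), type = "open")[seq_along(tt)]
  ch <- base * (1 + transients)
  out <- as.numeric(correct_bleaching(ch, tt))
  # fractional peak amplitude at each injected transient
  got <- vapply(peaks, function(p) {
    i <- round(p * fs) + 1
    max(out[i:(i + round(0.5 * fs))]) - 1
  }, numeric(1))
  expect_true(all(abs(got - 0.5) / 0.5 < 0.05))
})

test_that("bleach correction is idempotent", {
  fs <- 50
  tt <- seq(0, 200, by = 1 / fs)
  ch <- 50 + 30 * exp(-tt / 80)
  once <- as.numeric(correct_bleaching(ch, tt))
  twice <- as.numeric(suppressWarnings(correct_bleaching(once, tt)))
  expect_lt(sqrt(mean((twice - once)^2)), 1e-6)
})

test_that("constant channel passes through bleach correction as ~1", {
  tt <- seq(0, 50, by = 0.01)
  out <- suppressWarnings(correct_bleaching(rep(42, length(tt)), tt))
  expect_lt(max(abs(out - 1)), 1e-6)
  expect_error(correct_bleaching(c(-1, 1, 2), c(0, 1, 2)), "positive")
})

test_that("Savitzky-Golay control filtering has the textbook properties", {
  fs <- 100
  x <- rep(5, 600)
  expect_equal(filter_control(x, fs), x, tolerance = 1e-9)

  tt <- seq_len(600) / fs
  poly <- 2 + 3 * tt - 0.5 * tt^2 + 0.1 * tt^3
  sm <- filter_control(poly, fs)
  inner <- 80:520
  expect_lt(max(abs(sm[inner] - poly[inner])), 1e-9)

  set.seed(3)
  noise <- rnorm(2000)
  expect_lt(var(filter_control(noise, fs)), var(noise))

  expect_error(filter_control(x, fs, window_s = 0.02, polyorder = 3),
               "exceed")
})

test_that("dF/F handles degenerate and exact cases", {
  expect_equal(compute_dff(rep(3, 100), rep(3, 100)) |> as.numeric(),
               rep(0, 100))
  k <- 0.25
  expect_warning(
    dff <- compute_dff(rep(3 * (1 + k), 100), rep(3, 100)),
    "zero variance"
  )
  expect_equal(as.numeric(dff), rep(k, 100))
})

test_that("isosbestic regression removes shared artifacts by >= 90%", {
  set.seed(4)
  n <- 6000
  artifact <- numeric(n)
  spans <- lapply(seq(500, 5500, by = 1000), function(i) i:(i + 100))
  for (sp in spans) artifact[sp] <- 0.8
  sig <- (1 + artifact) * (1 + rnorm(n, 0, 0.005))
  ctl <- (1 + artifact) * (1 + rnorm(n, 0, 0.005))
  dff <- as.numeric(compute_dff(sig, ctl))
  naive <- sig / mean(sig) - 1
  amp_dff <- mean(abs(dff[unlist(spans)]))
  amp_naive <- mean(abs(naive[unlist(spans)]))
  expect_lt(amp_dff, 0.1 * amp_naive)
})

test_that("dF/F is invariant to common gain", {
  set.seed(5)
  n <- 3000
  tt <- (seq_len(n) - 1) / 100
  sig <- 100 * (1 + 0.3 * sin(tt)) + rnorm(n, 0, 0.5)
  ctl <- 80 * (1 + 0.3 * sin(tt)) + rnorm(n, 0, 0.5)
  d1 <- as.numeric(compute_dff(sig, ctl))
  d2 <- as.numeric(compute_dff(7.3 * sig, 7.3 * ctl))
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("z-scoring meets its contract", {
  z <- zscore_trace(c(0, 2))
  expect_equal(z, c(-sqrt(2) / 2, sqrt(2) / 2))
  set.seed(6)
  x <- rnorm(500, 3, 7)
  z <- zscore_trace(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(zscore_trace(5 * x + 2), z, tolerance = 1e-9)
  expect_error(zscore_trace(rep(1, 10)), "zero-variance")
  expect_error(zscore_trace(1), "2 samples")
})

test_that("full preprocessing yields flat CS-locked averages without CS input", {
  cfg <- tiny_config(n_trials_per_session = 10, noise_sd = 0.1,
                     locomotion_response_amplitude = 0,
                     air_response_amplitude = 0,
                     trial_type_fractions = c(paired = 1), seed = 8)
  sess <- simulate_session(cohort_spec("responsive", 1,
                                       cs_response_amplitude = 0), 1, cfg)
  tr <- suppressWarnings(process_recording(sess$recording))
  expect_equal(mean(tr$z), 0, tolerance = 1e-6)
  expect_equal(sd(tr$z), 1, tolerance = 1e-6)
  wins <- extract_trial_windows(tr, sess$trials)
  pooled <- pool_windows(wins)
  post <- pooled$mean_z[pooled$rel_time_s >= 0 & pooled$rel_time_s < 0.25]
  expect_lt(abs(mean(post)), 0.5)

  # responsive recording: clear positive CS-locked response
  sessR <- simulate_session(cohort_spec("responsive", 1), 1, cfg)
  trR <- suppressWarnings(process_recording(sessR$recording))
  pooledR <- pool_windows(extract_trial_windows(trR, sessR$trials))
  postR <- pooledR$mean_z[pooledR$rel_time_s >= 0 & pooledR$rel_time_s < 0.25]
  expect_gt(max(postR), 1)
})

test_that("artifact-rich and artifact-free simulations give similar z variance", {
  run_one <- function(rate) {
    cfg <- sim_config(sample_rate_hz = 50, n_sessions = 1,
                      n_trials_per_session = 30, iti_s = 1,
                      trial_type_fractions = c(paired = 1),
                      artifact_rate_hz = rate, seed = 12)
    sess <- simulate_session(cohort_spec("responsive", 1,
                                         cs_response_amplitude = 0), 1, cfg)
    tr <- suppressWarnings(process_recording(sess$recording))
    fs <- sample_rate(tr)
    mean(vapply(seq_len(nrow(sess$trials)), function(i) {
      i0 <- round(sess$trials$t_start_s[i] * fs) + 1
      i1 <- round(sess$trials$t_end_s[i] * fs) + 1
      var(tr$z[i0:i1])
    }, numeric(1)))
  }
  v_clean <- run_one(0)
  v_rich <- run_one(0.2)
  expect_lt(abs(v_rich - v_clean) / v_clean, 0.2)
})

test_that("provenance records the pipeline and round-trips", {
  cfg <- tiny_config(seed = 9)
  sess <- simulate_session(cohort_spec("responsive", 1), 1, cfg)
  tr <- suppressWarnings(process_recording(sess$recording))
  prov <- attr(tr, "provenance")
  expect_equal(prov$steps[1], "remove_artifacts")
  expect_equal(prov$sg_polyorder, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$z, tr$z, tolerance = 1e-12)
  expect_equal(attr(back, "provenance")$sg_polyorder, 3)
  expect_equal(sample_rate(back), sample_rate(tr))
})
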