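# Preprocessing: raw two-channel recording -> artifact-cleaned,
# bleach-corrected, isosbestic-regressed, z-scored trace.

#' Flag and interpolate shared motion artifacts
#'
#' Samples where *both* channels jointly deviate by more than
#' `threshold_mads` robust deviations from a 1-s rolling median are treated
#' as motion artifacts (the isosbestic rationale: true calcium transients
#' live only in the signal channel) and replaced by linear interpolation.
#'
#' @param rec An `fp_recording`.
#' @param threshold_mads Joint deviation threshold in MAD units.
#' @param window_s Rolling-median window (s).
#' @return The cleaned `fp_recording` with a logical attribute
#'   `artifact_mask` marking replaced samples.
#' @export
remove_artifacts <- function(rec, threshold_mads = 8, window_s = 1) {
  stopifnot(inherits(rec, "fp_recording"))
  fs <- sample_rate(rec)
  k <- odd_window(window_s * fs, nrow(rec))
  dev_s <- rec$signal - stats::runmed(rec$signal, k)
  dev_c <- rec$control - stats::runmed(rec$control, k)
  mad_s <- mad(dev_s)
  mad_c <- mad(dev_c)
  if (mad_s == 0 || mad_c == 0) {
    mask <- rep(FALSE, nrow(rec))
  } else {
    mask <- abs(dev_s) > threshold_mads * mad_s &
      abs(dev_c) > threshold_mads * mad_c
  }
  if (all(mask)) abort("every sample was flagged as artifact; recording unusable.")
  out <- rec
  if (any(mask)) {
    keep <- which(!mask)
    out$signal <- approx(rec$time_s[keep], rec$signal[keep], rec$time_s,
                         rule = 2)$y
    out$control <- approx(rec$time_s[keep], rec$control[keep], rec$time_s,
                          rule = 2)$y
  }
  attr(out, "artifact_mask") <- mask
  out
}

odd_window <- function(n_samples, n_total) {
  k <- max(3L, round(n_samples))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= n_total) k <- if (n_total %% 2 == 1) n_total - 2L else n_total - 1L
  max(3L, k)
}

#' Correct exponential photobleaching
#'
#' Fits `a + b * exp(-t / tau)` by least squares and divides the channel by
#' the fitted curve, so the output fluctuates around 1. The fit is performed
#' on a rolling-median (5-s) version of the channel so that sparse positive
#' transients do not bias the baseline; for a transient-free exponential
#' this leaves the fit unchanged away from the edges. A non-convergent fit
#' falls back to a linear detrend with a warning.
#'
#' @param channel Strictly positive fluorescence vector.
#' @param time_s Matching time vector (s).
#' @return Detrended channel with attributes `fit` (named vector `a`, `b`,
#'   `tau`, or `intercept`/`slope` for the fallback) and `method`
#'   (`"exponential"` or `"linear"`).
#' @export
correct_bleaching <- function(channel, time_s) {
  if (any(channel <= 0)) abort("`channel` must be strictly positive.")
  n <- length(channel)
  fs <- 1 / median(diff(time_s))
  k <- odd_window(5 * fs, n)
  base <- stats::runmed(channel, k)
  t0 <- time_s - time_s[1]
  span <- max(t0[n], 1e-9)
  start <- list(a = min(base), b = max(base[1] - min(base), 1e-3 * mean(base)),
                tau = span / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a + b * exp(-tt / tau),
      data = list(y = base, tt = t0),
      start = start,
      lower = c(a = 0, b = 0, tau = span * 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- coef(fit)
    curve <- p[["a"]] + p[["b"]] * exp(-t0 / p[["tau"]])
    if (all(curve > 0)) {
      out <- channel / curve
      attr(out, "fit") <- c(a = p[["a"]], b = p[["b"]], tau = p[["tau"]])
      attr(out, "method") <- "exponential"
      return(out)
    }
  }
  warn("exponential bleach fit did not converge; falling back to linear detrend.")
  lf <- lm(base ~ t0)
  curve <- pmax(fitted(lf), 1e-9 * mean(channel))
  out <- channel / as.numeric(curve)
  attr(out, "fit") <- c(intercept = unname(coef(lf)[1]), slope = unname(coef(lf)[2]))
  attr(out, "method") <- "linear"
  out
}

#' Savitzky-Golay smoothing of the isosbestic control channel
#'
#' Removes high-frequency noise from the 410-nm control channel while
#' preserving the slow drift that the dF/F regression must track.
#'
#' @param control Control-channel vector.
#' @param sample_rate_hz Sample rate (Hz).
#' @param window_s Filter window length (s); rounded to an odd number of
#'   samples.
#' @param polyorder Polynomial order (must be < window length in samples).
#' @return Smoothed vector, same length.
#' @export
filter_control <- function(control, sample_rate_hz, window_s = 1.001,
                           polyorder = 3) {
  k <- odd_window(window_s * sample_rate_hz, length(control))
  if (k <= polyorder) {
    abort(sprintf("filter window (%d samples) must exceed `polyorder` (%d).",
                  k, polyorder))
  }
  as.numeric(signal::sgolayfilt(control, p = polyorder, n = k))
}

#' Isosbestic-regressed dF/F
#'
#' Regresses the (filtered, bleach-corrected) control channel onto the
#' signal channel by ordinary least squares (scale + offset) and forms
#' `dff = (signal - fitted_control) / fitted_control`. Because motion
#' artifacts enter both channels proportionally, the fitted control tracks
#' and removes them; calcium transients, absent from the control, survive.
#'
#' @param signal Bleach-corrected signal channel.
#' @param control_filtered Bleach-corrected, filtered control channel.
#' @return dF/F vector with attribute `fit` (intercept, slope of the
#'   control-to-signal regression).
#' @export
compute_dff <- function(signal, control_filtered) {
  if (length(signal) != length(control_filtered)) {
    abort("`signal` and `control_filtered` must have equal length.")
  }
  if (stats::sd(control_filtered) == 0) {
    warn("control channel has zero variance; using its level as the baseline.")
    m <- mean(control_filtered)
    if (m == 0) m <- mean(signal)
    out <- (signal - m) / m
    attr(out, "fit") <- c(intercept = m, slope = 0)
    return(out)
  }
  fit <- lm(signal ~ control_filtered)
  fitted_control <- as.numeric(fitted(fit))
  fitted_control <- pmax(fitted_control, 1e-9 * mean(abs(signal)))
  out <- (signal - fitted_control) / fitted_control
  attr(out, "fit") <- c(intercept = unname(coef(fit)[1]),
                        slope = unname(coef(fit)[2]))
  out
}

#' z-score a dF/F trace
#'
#' Centers and scales by the sample standard deviation (denominator n - 1)
#' over the whole vector, the normalization span used before any windowing.
#'
#' @param dff dF/F vector (>= 2 samples, nonzero variance).
#' @return z-scored vector: mean 0, sample SD 1.
#' @export
zscore_trace <- function(dff) {
  if (length(dff) < 2L) abort("z-scoring needs at least 2 samples.")
  s <- stats::sd(dff)
  if (s == 0) abort("z-scoring is undefined for a zero-variance trace.")
  as.numeric((dff - mean(dff)) / s)
}

#' Full preprocessing pipeline for one recording
#'
#' Composition: artifact removal (joint-channel MAD rule) -> exponential
#' bleach correction of both channels -> Savitzky-Golay filtering of the
#' control -> isosbestic-regressed dF/F -> z-scoring over the whole
#' recording. Every parameter is recorded in the trace's provenance.
#'
#' @param rec An `fp_recording`.
#' @param artifact_threshold_mads Joint artifact threshold (MADs).
#' @param artifact_window_s Rolling-median window for artifact detection (s).
#' @param sg_window_s,sg_polyorder Savitzky-Golay window (s) and order.
#' @return An `fp_trace` tibble (`time_s`, `dff`, `z`) with attributes
#'   `sample_rate_hz`, `provenance` (list of steps and parameters) and
#'   `artifact_mask`.
#' @export
#' @examples
#' cfg <- sim_config(sample_rate_hz = 100, n_trials_per_session = 4,
#'                   n_sessions = 1, seed = 3)
#' sess <- simulate_session(cohort_spec("responsive", 1), 1, cfg)
#' tr <- process_recording(sess$recording)
#' round(c(mean(tr$z), sd(tr$z)), 6)
process_recording <- function(rec,
                              artifact_threshold_mads = 8,
                              artifact_window_s = 1,
                              sg_window_s = 1.001,
                              sg_polyorder = 3) {
  stopifnot(inherits(rec, "fp_recording"))
  fs <- sample_rate(rec)
  clean <- remove_artifacts(rec, artifact_threshold_mads, artifact_window_s)
  sig_b <- correct_bleaching(clean$signal, clean$time_s)
  ctl_b <- correct_bleaching(clean$control, clean$time_s)
  ctl_f <- filter_control(as.numeric(ctl_b), fs, sg_window_s, sg_polyorder)
  dff <- compute_dff(as.numeric(sig_b), ctl_f)
  z <- zscore_trace(as.numeric(dff))
  out <- tibble(time_s = rec$time_s, dff = as.numeric(dff), z = z)
  attr(out, "sample_rate_hz") <- fs
  attr(out, "artifact_mask") <- attr(clean, "artifact_mask")
  attr(out, "provenance") <- list(
    steps = c("remove_artifacts", "correct_bleaching", "filter_control",
              "compute_dff", "zscore_trace"),
    artifact_threshold_mads = artifact_threshold_mads,
    artifact_window_s = artifact_window_s,
    n_artifact_samples = sum(attr(clean, "artifact_mask")),
    bleach_method_signal = attr(sig_b, "method"),
    bleach_method_control = attr(ctl_b, "method"),
    bleach_fit_signal = as.list(attr(sig_b, "fit")),
    bleach_fit_control = as.list(attr(ctl_b, "fit")),
    sg_window_s = sg_window_s,
    sg_polyorder = sg_polyorder,
    dff_fit = as.list(attr(dff, "fit")),
    zscore_span = "recording"
  )
  class(out) <- c("fp_trace", class(out))
  out
}
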