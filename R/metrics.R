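# Per-trial scalar metrics on stimulus-locked windows, pooled responses,
# and the combined step-time/photometry Euclidean statistic.

# index of the t = 0 sample and number of samples in [0, isi)
csus_indices <- function(window, isi_s) {
  fs <- sample_rate(window)
  i0 <- which.min(abs(window$rel_time_s))
  n_in <- round(isi_s * fs)
  if (n_in < 1L || i0 + n_in - 1L > nrow(window)) {
    abort(sprintf("window does not cover the [0, %.3f) s epoch.", isi_s))
  }
  list(i0 = i0, idx = i0:(i0 + n_in - 1L))
}

#' Mean z in the CS--US window
#'
#' Arithmetic mean of the z samples with relative time in the half-open
#' interval `[0, isi_s)`, the anticipatory epoch between CS and US onsets.
#'
#' @param window An `fp_window`.
#' @param isi_s CS--US interstimulus interval (s).
#' @return Scalar mean z.
#' @export
mean_z_csus <- function(window, isi_s = 0.25) {
  ix <- csus_indices(window, isi_s)
  mean(window$z[ix$idx])
}

#' Delta-z between US and CS onsets
#'
#' z at the sample nearest `t = isi_s` minus z at the sample nearest
#' `t = 0` (no interpolation).
#'
#' @inheritParams mean_z_csus
#' @return Scalar delta-z.
#' @export
delta_z <- function(window, isi_s = 0.25) {
  i0 <- which.min(abs(window$rel_time_s))
  i1 <- which.min(abs(window$rel_time_s - isi_s))
  if (i1 <= i0 && isi_s > 0) abort("window does not cover the US onset.")
  window$z[i1] - window$z[i0]
}

#' Rate of change of the signal across the CS--US window
#'
#' Ordinary-least-squares slope of z against relative time over the samples
#' in `[0, isi_s)`, in z-units per second.
#'
#' @inheritParams mean_z_csus
#' @return Scalar slope (z/s).
#' @export
csus_slope <- function(window, isi_s = 0.25) {
  ix <- csus_indices(window, isi_s)
  if (length(ix$idx) < 2L) abort("slope needs at least 2 samples in the window.")
  x <- window$rel_time_s[ix$idx]
  y <- window$z[ix$idx]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' All scalar window metrics for one window
#'
#' @inheritParams mean_z_csus
#' @return One-row tibble: `z_mean_csus`, `z_cs`, `z_us`, `delta_z`,
#'   `slope`.
#' @export
window_metrics <- function(window, isi_s = 0.25) {
  i0 <- which.min(abs(window$rel_time_s))
  i1 <- which.min(abs(window$rel_time_s - isi_s))
  tibble(
    z_mean_csus = mean_z_csus(window, isi_s),
    z_cs = window$z[i0],
    z_us = window$z[i1],
    delta_z = window$z[i1] - window$z[i0],
    slope = csus_slope(window, isi_s)
  )
}

# vectorized window_metrics over a list of same-shape windows (hot path)
window_metrics_table <- function(windows, isi_s = 0.25) {
  m <- vapply(windows, function(w) {
    fs <- attr(w, "sample_rate_hz")
    i0 <- which.min(abs(w$rel_time_s))
    n_in <- round(isi_s * fs)
    if (n_in < 1L || i0 + n_in - 1L > length(w$z)) {
      abort(sprintf("window does not cover the [0, %.3f) s epoch.", isi_s))
    }
    idx <- i0:(i0 + n_in - 1L)
    i1 <- which.min(abs(w$rel_time_s - isi_s))
    x <- w$rel_time_s[idx]
    y <- w$z[idx]
    xc <- x - mean(x)
    c(mean(y), w$z[i0], w$z[i1], w$z[i1] - w$z[i0],
      sum(xc * (y - mean(y))) / sum(xc^2))
  }, numeric(5))
  tibble(z_mean_csus = m[1, ], z_cs = m[2, ], z_us = m[3, ],
         delta_z = m[4, ], slope = m[5, ])
}

#' z-score step times within a normalization span
#'
#' @param values Positive step times (ms).
#' @param group Optional grouping vector defining the normalization span;
#'   `NULL` normalizes over the whole vector.
#' @return z-scored values (sample SD).
#' @export
#' @examples
#' zscore_steptimes(c(1, 2, 3))
zscore_steptimes <- function(values, group = NULL) {
  zs <- function(x) {
    if (length(x) < 2L) abort("z-scoring needs >= 2 values per span.")
    s <- stats::sd(x)
    if (s == 0) abort("z-scoring is undefined for zero-variance step times.")
    (x - mean(x)) / s
  }
  if (is.null(group)) return(zs(values))
  out <- numeric(length(values))
  for (g in unique(group)) {
    sel <- group == g
    out[sel] <- zs(values[sel])
  }
  out
}

#' Combined step-time/photometry Euclidean statistic
#'
#' log2 of the Euclidean distance between the points
#' (z pre-perturbation step time, z dF/F at CS onset) and
#' (z post-perturbation step time, z dF/F at US onset):
#' `log2(sqrt((z_post - z_pre)^2 + (z_us - z_cs)^2))`. With
#' `squared = TRUE` the literal squared-distance form
#' `log2((z_post - z_pre)^2 + (z_us - z_cs)^2)` is returned instead
#' (exactly twice the default, so ranks and sign comparisons are
#' preserved). Zero-distance trials are undefined and return `NA` with a
#' message.
#'
#' @param z_pre,z_post z-scored pre-/post-perturbation step times.
#' @param z_cs,z_us z-scored dF/F at CS (t = 0) and US (t = isi) onsets.
#' @param squared Use the literal squared-distance form.
#' @return Numeric vector (NA where the distance is zero).
#' @export
#' @examples
#' euclid_log2_distance(0, 3, 0, 4) # log2(5)
euclid_log2_distance <- function(z_pre, z_post, z_cs, z_us, squared = FALSE) {
  d2 <- (z_post - z_pre)^2 + (z_us - z_cs)^2
  zero <- d2 == 0
  if (any(zero)) {
    inform(sprintf(
      "%d trial(s) with zero step-time/photometry distance excluded (log undefined).",
      sum(zero)))
  }
  out <- ifelse(zero, NA_real_, log2(d2))
  if (!squared) out <- out / 2
  out
}

#' Pool stimulus-locked windows across trials
#'
#' Pointwise mean across trials with a pointwise t-based confidence band.
#'
#' @param windows List of `fp_window` objects (or a list-column), all on the
#'   same relative-time grid.
#' @param level Confidence level.
#' @return An `fp_pooled` tibble (`rel_time_s`, `mean_z`, `lwr`, `upr`)
#'   with attributes `n_trials` and `level`.
#' @export
pool_windows <- function(windows, level = 0.95) {
  if (is_tibble(windows) && "window" %in% names(windows)) {
    windows <- windows$window
  }
  if (!length(windows)) abort("no windows to pool.")
  grid <- windows[[1]]$rel_time_s
  same <- map_lgl(windows, function(w) {
    length(w$rel_time_s) == length(grid) &&
      max(abs(w$rel_time_s - grid)) < 1e-9
  })
  if (!all(same)) abort("windows are on mixed relative-time grids.")
  zmat <- vapply(windows, function(w) w$z, numeric(length(grid)))
  zmat <- matrix(zmat, nrow = length(grid))
  n <- ncol(zmat)
  m <- rowMeans(zmat)
  if (n > 1L) {
    se <- apply(zmat, 1, stats::sd) / sqrt(n)
    tq <- qt(1 - (1 - level) / 2, df = n - 1)
    lwr <- m - tq * se
    upr <- m + tq * se
  } else {
    lwr <- upr <- m
  }
  out <- tibble(rel_time_s = grid, mean_z = m, lwr = lwr, upr = upr)
  attr(out, "n_trials") <- n
  attr(out, "level") <- level
  class(out) <- c("fp_pooled", class(out))
  out
}

#' Assemble the regression-ready per-trial analysis table
#'
#' Joins behavioral step times with the window metrics, z-scores the step
#' times over the chosen span, and computes the log2 Euclidean statistic.
#' Rows with missing metrics are excluded with a message; duplicated trial
#' keys are an error.
#'
#' @param tbl Per-trial tibble with at least `trial_index`, `pre_step_ms`,
#'   `post_step_ms`, `z_cs`, `z_us` and, when present, `cohort`, `mouse`,
#'   `session`, `duration_s`, `velocity`.
#' @param span Normalization span for step-time z-scores: `"pooled"` (whole
#'   table, the default, so cohort differences survive on the z scale),
#'   `"per_group"`, `"per_mouse"` or `"per_session"`.
#' @param squared Passed to [euclid_log2_distance()].
#' @return The table with `z_pre`, `z_post`, `euclid_log2` columns added.
#' @export
behavior_regressors <- function(tbl, span = c("pooled", "per_group",
                                              "per_mouse", "per_session"),
                                squared = FALSE) {
  span <- match.arg(span)
  need <- c("trial_index", "pre_step_ms", "post_step_ms", "z_cs", "z_us")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!nrow(tbl)) {
    return(tbl |> mutate(z_pre = numeric(0), z_post = numeric(0),
                         euclid_log2 = numeric(0)))
  }
  key_cols <- intersect(c("cohort", "mouse", "session", "trial_index"), names(tbl))
  keys <- do.call(paste, c(tbl[key_cols], sep = "\r"))
  if (anyDuplicated(keys)) abort("duplicated trial indices in the metric table.")
  ok <- complete.cases(tbl[, need])
  if (any(!ok)) {
    inform(sprintf("%d trial(s) with missing metrics excluded.", sum(!ok)))
    tbl <- tbl[ok, ]
  }
  grp <- switch(span,
    pooled = NULL,
    per_group = tbl$cohort %||% abort("`per_group` span needs a `cohort` column."),
    per_mouse = tbl$mouse %||% abort("`per_mouse` span needs a `mouse` column."),
    per_session = paste(tbl$cohort %||% "", tbl$session %||%
                          abort("`per_session` span needs a `session` column."))
  )
  tbl |>
    mutate(
      z_pre = zscore_steptimes(.data$pre_step_ms, grp),
      z_post = zscore_steptimes(.data$post_step_ms, grp),
      euclid_log2 = euclid_log2_distance(.data$z_pre, .data$z_post,
                                         .data$z_cs, .data$z_us,
                                         squared = squared)
    )
}
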