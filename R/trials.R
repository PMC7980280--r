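# Trial segmentation from event streams, trial-type classification, and
# stimulus-locked window extraction.

event_kinds <- c("air_cue", "trial_start", "cs_onset", "us_onset", "trial_end")

#' Segment trials from an event stream
#'
#' Pairs each `trial_start` with the next `trial_end` that precedes any
#' further `trial_start`. Unmatched markers (a start with no end before the
#' next start, or an end with no preceding open start) are dropped and
#' listed in the orphan report, never repaired.
#'
#' @param events Tibble with `timestamp_s`, `event_type` (sorted or not;
#'   sorted internally).
#' @return Tibble of intervals (`t_start_s`, `t_end_s`), in order, with an
#'   `orphans` attribute (tibble of dropped markers).
#' @export
segment_trials <- function(events) {
  events <- validate_events(events)
  bm <- events |> filter(.data$event_type %in% c("trial_start", "trial_end"))
  starts <- numeric(0)
  ends <- numeric(0)
  orphan_t <- numeric(0)
  orphan_k <- character(0)
  open_start <- NA_real_
  for (i in seq_len(nrow(bm))) {
    tsi <- bm$timestamp_s[i]
    if (bm$event_type[i] == "trial_start") {
      if (!is.na(open_start)) {
        orphan_t <- c(orphan_t, open_start)
        orphan_k <- c(orphan_k, "trial_start")
      }
      open_start <- tsi
    } else {
      if (is.na(open_start)) {
        orphan_t <- c(orphan_t, tsi)
        orphan_k <- c(orphan_k, "trial_end")
      } else {
        starts <- c(starts, open_start)
        ends <- c(ends, tsi)
        open_start <- NA_real_
      }
    }
  }
  if (!is.na(open_start)) {
    orphan_t <- c(orphan_t, open_start)
    orphan_k <- c(orphan_k, "trial_start")
  }
  out <- tibble(t_start_s = starts, t_end_s = ends)
  attr(out, "orphans") <- tibble(timestamp_s = orphan_t, event_type = orphan_k)
  out
}

validate_events <- function(events) {
  if (!all(c("timestamp_s", "event_type") %in% names(events))) {
    abort("events need columns `timestamp_s` and `event_type`.")
  }
  bad <- setdiff(unique(events$event_type), event_kinds)
  if (length(bad)) {
    abort(sprintf("unknown event kind(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.unsorted(events$timestamp_s)) {
    events <- events |> arrange(.data$timestamp_s)
  }
  events
}

#' Classify one trial interval
#'
#' A trial is `paired` if it contains at least one CS and one US onset,
#' `cs_only`/`us_only` with only one of the two, and `unperturbed` with
#' neither. The first occurrence of each kind is the canonical timestamp.
#'
#' @param events Event tibble.
#' @param t_start_s,t_end_s Trial interval (closed).
#' @return List with `type`, `t_cs_s`, `t_us_s` (NA when absent).
#' @export
classify_trial <- function(events, t_start_s, t_end_s) {
  inside <- events |>
    filter(.data$timestamp_s >= t_start_s, .data$timestamp_s <= t_end_s)
  cs <- inside$timestamp_s[inside$event_type == "cs_onset"]
  us <- inside$timestamp_s[inside$event_type == "us_onset"]
  type <- if (length(cs) && length(us)) "paired"
  else if (length(cs)) "cs_only"
  else if (length(us)) "us_only"
  else "unperturbed"
  list(type = type,
       t_cs_s = if (length(cs)) cs[1] else NA_real_,
       t_us_s = if (length(us)) us[1] else NA_real_)
}

#' Segment and classify all trials in an event stream
#'
#' Runs [segment_trials()] then [classify_trial()] on each interval, and
#' flags trials whose start precedes the nearest preceding air cue
#' (`left_before_cue`): the air cue associated with a trial is the last cue
#' at or before the trial start, or the first cue after it when the animal
#' left the goal box early.
#'
#' @param events Event tibble.
#' @return Trial tibble (`trial_index`, `type`, `t_start_s`, `t_end_s`,
#'   `t_cs_s`, `t_us_s`, `t_air_s`, `left_before_cue`, `duration_s`) with
#'   the `orphans` attribute from segmentation.
#' @export
annotate_trials <- function(events) {
  events <- validate_events(events)
  iv <- segment_trials(events)
  n <- nrow(iv)
  ts <- events$timestamp_s
  kind <- events$event_type
  cs_times <- ts[kind == "cs_onset"]
  us_times <- ts[kind == "us_onset"]
  air <- ts[kind == "air_cue"]
  t_cs <- t_us <- t_air <- rep(NA_real_, n)
  type <- character(n)
  left <- logical(n)
  for (i in seq_len(n)) {
    a <- iv$t_start_s[i]; b <- iv$t_end_s[i]
    cs_in <- cs_times[cs_times >= a & cs_times <= b]
    us_in <- us_times[us_times >= a & us_times <= b]
    if (length(cs_in)) t_cs[i] <- cs_in[1]
    if (length(us_in)) t_us[i] <- us_in[1]
    type[i] <- if (length(cs_in) && length(us_in)) "paired"
    else if (length(cs_in)) "cs_only"
    else if (length(us_in)) "us_only"
    else "unperturbed"
    # air cue owned by this trial: last cue at/before the start, or the
    # first later cue (before the next trial) when the animal left early
    upper <- if (i < n) iv$t_start_s[i + 1] else Inf
    cand <- air[air < upper]
    if (length(cand)) {
      before <- cand[cand <= a]
      t_air[i] <- if (length(before)) max(before) else min(cand[cand > a])
      left[i] <- a < t_air[i]
    }
  }
  out <- tibble(trial_index = seq_len(n), type = type,
                t_start_s = iv$t_start_s, t_end_s = iv$t_end_s,
                t_cs_s = t_cs, t_us_s = t_us, t_air_s = t_air,
                left_before_cue = left,
                duration_s = iv$t_end_s - iv$t_start_s)
  attr(out, "orphans") <- attr(iv, "orphans")
  out
}

#' Extract a stimulus-locked z-score window
#'
#' Returns the z samples in the half-open interval `[t0 - pre_s, t0 +
#' post_s)`, with t = 0 assigned to the sample nearest `t0` (no
#' interpolation). The default 2-s span (0.5 s before, 1.5 s after) brackets
#' the 250-ms CS--US epoch.
#'
#' @param trace An `fp_trace` from [process_recording()].
#' @param t0_s Alignment time (s), e.g. CS onset.
#' @param pre_s,post_s Window extent before/after `t0_s` (s).
#' @param t0_kind Label for the alignment event.
#' @return An `fp_window` tibble (`rel_time_s`, `z`) with attributes
#'   `sample_rate_hz` and `t0_kind`.
#' @export
extract_window <- function(trace, t0_s, pre_s = 0.5, post_s = 1.5,
                           t0_kind = "cs_onset") {
  fs <- sample_rate(trace)
  n <- nrow(trace)
  i0 <- round((t0_s - trace$time_s[1]) * fs) + 1L
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  lo <- i0 - n_pre
  hi <- i0 + n_post - 1L
  if (lo < 1L || hi > n) {
    abort(sprintf(
      "window [%.3f, %.3f] s around t0 = %.3f s exceeds the recording bounds.",
      t0_s - pre_s, t0_s + post_s, t0_s))
  }
  idx <- lo:hi
  out <- tibble::new_tibble(
    list(rel_time_s = (idx - i0) / fs, z = trace$z[idx]),
    nrow = length(idx), class = "fp_window"
  )
  attr(out, "sample_rate_hz") <- fs
  attr(out, "t0_kind") <- t0_kind
  out
}

#' Extract CS/US-locked windows for every eligible trial
#'
#' Paired and CS-only trials align to CS onset; US-only trials align to US
#' onset; unperturbed trials have no alignment event and are skipped.
#' Trials whose window would exceed the recording are skipped with a
#' warning.
#'
#' @param trace An `fp_trace`.
#' @param trials Trial tibble (from [annotate_trials()] or the simulator).
#' @inheritParams extract_window
#' @return Tibble with `trial_index`, `type`, `t0_kind`, `t0_s` and a
#'   list-column `window` of `fp_window` objects.
#' @export
extract_trial_windows <- function(trace, trials, pre_s = 0.5, post_s = 1.5) {
  n <- nrow(trials)
  kind <- ifelse(trials$type %in% c("paired", "cs_only"), "cs_onset",
                 ifelse(trials$type == "us_only", "us_onset", NA_character_))
  t0 <- ifelse(kind == "cs_onset", trials$t_cs_s,
               ifelse(kind == "us_onset", trials$t_us_s, NA_real_))
  keep <- which(!is.na(kind) & !is.na(t0))
  wins <- vector("list", length(keep))
  ok <- rep(TRUE, length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    w <- tryCatch(extract_window(trace, t0[i], pre_s, post_s, kind[i]),
                  error = function(e) NULL)
    if (is.null(w)) {
      warn(sprintf("trial %d: window out of bounds; skipped.",
                   trials$trial_index[i]))
      ok[j] <- FALSE
    } else {
      wins[[j]] <- w
    }
  }
  keep <- keep[ok]
  tibble(trial_index = trials$trial_index[keep], type = trials$type[keep],
         t0_kind = kind[keep], t0_s = t0[keep], window = wins[ok])
}

#' Extract air-cue-locked windows
#'
#' One window per pretrial air cue (the cue for the mouse to leave the goal
#' box); cues too close to the recording bounds are skipped with a warning.
#'
#' @param trace An `fp_trace`.
#' @param events Event tibble containing `air_cue` rows.
#' @inheritParams extract_window
#' @return Tibble with `t0_s` and list-column `window`.
#' @export
extract_airpuff_windows <- function(trace, events, pre_s = 0.5, post_s = 1.5) {
  events <- validate_events(events)
  cues <- events$timestamp_s[events$event_type == "air_cue"]
  if (!length(cues)) abort("no `air_cue` events in the stream.")
  rows <- map(cues, function(t0) {
    w <- tryCatch(extract_window(trace, t0, pre_s, post_s, "air_cue"),
                  error = function(e) NULL)
    if (is.null(w)) {
      warn(sprintf("air cue at %.3f s: window out of bounds; skipped.", t0))
      return(NULL)
    }
    tibble(t0_s = t0, window = list(w))
  })
  out <- list_rbind(rows)
  if (is.null(out) || !nrow(out)) out <- tibble(t0_s = numeric(), window = list())
  out
}
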