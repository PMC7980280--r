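# Plain-text readers/writers for recordings, traces, event streams and
# trial tables, plus the YAML analysis configuration. Metadata (sample rate,
# provenance) rides as `#`-prefixed header lines above the CSV header.

write_meta_csv <- function(df, path, meta = list()) {
  lines <- map_chr(names(meta), function(nm) {
    sprintf("# %s: %s", nm,
            if (is.character(meta[[nm]]) && length(meta[[nm]]) == 1L)
              meta[[nm]]
            else jsonlite::toJSON(meta[[nm]], auto_unbox = TRUE, digits = NA))
  })
  writeLines(lines, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Write / read a raw two-channel recording (CSV dialect)
#'
#' Columns `time_s`, `signal`, `control`; the sample rate is stored in a
#' `# sample_rate_hz:` header line and cross-checked against the time grid
#' on read.
#'
#' @param rec An `fp_recording`.
#' @param path File path.
#' @return `write_recording()` the path, invisibly; `read_recording()` a
#'   validated `fp_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  write_meta_csv(as_tibble(rec), path,
                 list(sample_rate_hz = format(sample_rate(rec), digits = 15)))
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  meta <- read_meta(path)
  if (is.null(meta$sample_rate_hz)) {
    abort(sprintf("%s: missing `# sample_rate_hz:` header.", path))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("time_s", "signal", "control")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  bad <- !complete.cases(df[, need])
  if (any(bad)) {
    abort(sprintf("%s: channel length mismatch or missing values at row %d.",
                  path, which(bad)[1]))
  }
  new_recording(df$time_s, df$signal, df$control,
                as.numeric(meta$sample_rate_hz))
}

#' Write / read a processed trace (CSV dialect)
#'
#' Columns `time_s`, `dff`, `z`; sample rate and the provenance record are
#' stored as header lines (`# provenance:` holds JSON) and restored on
#' read.
#'
#' @param trace An `fp_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fp_trace"))
  write_meta_csv(
    as_tibble(trace), path,
    list(sample_rate_hz = format(sample_rate(trace), digits = 15),
         provenance = attr(trace, "provenance"))
  )
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- read_meta(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  out <- tibble(time_s = df$time_s, dff = df$dff, z = df$z)
  attr(out, "sample_rate_hz") <- as.numeric(meta$sample_rate_hz)
  if (!is.null(meta$provenance)) {
    attr(out, "provenance") <- jsonlite::fromJSON(meta$provenance)
  }
  class(out) <- c("fp_trace", class(out))
  out
}

#' Write / read an event stream (CSV)
#'
#' Columns `timestamp_s`, `event_type`; unknown event kinds are an error
#' naming the offending value; unsorted timestamps are sorted on read with
#' a warning.
#'
#' @param events Event tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("timestamp_s", "event_type") %in% names(df))) {
    abort(sprintf("%s: expected columns timestamp_s, event_type.", path))
  }
  bad <- setdiff(unique(df$event_type), event_kinds)
  if (length(bad)) {
    abort(sprintf("%s: unknown event kind \"%s\".", path, bad[1]))
  }
  if (is.unsorted(df$timestamp_s)) {
    warn(sprintf("%s: timestamps out of order; sorting.", path))
    df <- df |> arrange(.data$timestamp_s)
  }
  df
}

#' Write / read a trial table (CSV)
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if ("type" %in% names(df)) {
    bad <- setdiff(unique(df$type), trial_types)
    if (length(bad)) {
      abort(sprintf("%s: unknown trial type \"%s\".", path, bad[1]))
    }
  }
  df
}

analysis_config_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(
      sample_rate_hz = 100,
      n_sessions = 3L,
      n_trials_per_session = 72L,
      trial_type_fractions = list(unperturbed = 0.40, cs_only = 0.175,
                                  us_only = 0.175, paired = 0.25),
      noise_sd = 0.3,
      cohorts = list(
        list(label = "responsive", n_mice = 3L),
        list(label = "attenuated", n_mice = 3L)
      )
    ),
    preprocess = list(
      artifact_threshold_mads = 8,
      artifact_window_s = 1,
      sg_window_s = 1.001,
      sg_polyorder = 3L
    ),
    window = list(pre_s = 0.5, post_s = 1.5),
    metrics = list(isi_s = 0.25, steptime_span = "pooled", squared = FALSE),
    stats = list(rout_q_percent = 1, alpha = 0.05),
    log_level = "info"
  )
}

#' Analysis configuration
#'
#' Builds the full pipeline configuration (simulation, preprocessing,
#' window, metric and statistics parameters) by merging overrides into the
#' defaults. Unknown keys are rejected; the configuration round-trips
#' through YAML losslessly.
#'
#' @param ... Named overrides; nested sections may be partial lists.
#' @return A named list of class `fp_analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config(seed = 42, window = list(pre_s = 0.25))
#' cfg$window$pre_s
analysis_config <- function(...) {
  overrides <- list(...)
  merge_config(analysis_config_defaults(), overrides, path = "")
}

merge_config <- function(base, overrides, path = "") {
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" in ", path) else "",
                  paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    free_form <- nm %in% c("trial_type_fractions", "cohorts")
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) && !free_form) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]],
                                 path = paste0(path, nm, "."))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  class(base) <- unique(c("fp_analysis_config", class(base)))
  base
}

#' Read / write an analysis configuration (YAML)
#'
#' @param path YAML file path.
#' @param config Configuration from [analysis_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  yaml::write_yaml(plain, path)
  invisible(path)
}
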