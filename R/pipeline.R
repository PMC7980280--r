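# End-to-end orchestration: simulate -> preprocess -> segment/window ->
# metrics -> group statistics, with all artifacts written as plain text.

#' Per-trial analysis table for a simulated (or loaded) dataset
#'
#' For every mouse-session: preprocesses the recording, re-derives the
#' trial intervals and types from the event stream, extracts CS/US-locked
#' windows, computes the scalar window metrics, and joins the behavioral
#' step times. Segmentation and classification come from the events, not
#' from the simulator's bookkeeping, so the full analysis path is
#' exercised.
#'
#' @param dataset Nested tibble from [simulate_cohort()] (columns `cohort`,
#'   `mouse`, `session`, list-columns `recording`, `events`, `trials`).
#' @param pre_s,post_s Window extent around the alignment event (s).
#' @param isi_s CS--US interval (s) for the metric epoch.
#' @param preprocess Named list of overrides passed to
#'   [process_recording()].
#' @return Per-trial tibble: identifiers, trial type and times, behavior
#'   (`pre_step_ms`, `post_step_ms`, `duration_s`, `velocity`,
#'   `left_before_cue`) and window metrics (`z_mean_csus`, `z_cs`, `z_us`,
#'   `delta_z`, `slope`).
#' @export
analyze_dataset <- function(dataset, pre_s = 0.5, post_s = 1.5, isi_s = 0.25,
                            preprocess = list()) {
  analyze_dataset_full(dataset, pre_s, post_s, isi_s, preprocess)$analysis
}

# shared worker: per-trial metrics plus the windows themselves
analyze_dataset_full <- function(dataset, pre_s = 0.5, post_s = 1.5,
                                 isi_s = 0.25, preprocess = list()) {
  met_rows <- list()
  win_rows <- list()
  for (i in seq_len(nrow(dataset))) {
    trace <- do.call(process_recording,
                     c(list(dataset$recording[[i]]), preprocess))
    derived <- annotate_trials(dataset$events[[i]])
    wins <- extract_trial_windows(trace, derived, pre_s = pre_s,
                                  post_s = post_s)
    if (!nrow(wins)) next
    mets <- window_metrics_table(wins$window, isi_s = isi_s)
    behav <- dataset$trials[[i]] |>
      select(any_of(c("trial_index", "pre_step_ms", "post_step_ms",
                      "duration_s", "velocity")))
    met_rows[[length(met_rows) + 1L]] <- wins |>
      select("trial_index", "type", "t0_kind") |>
      bind_cols(mets) |>
      left_join(derived |> select("trial_index", "left_before_cue"),
                by = "trial_index") |>
      left_join(behav, by = "trial_index") |>
      mutate(cohort = dataset$cohort[i], mouse = dataset$mouse[i],
             session = dataset$session[i], .before = 1)
    win_rows[[length(win_rows) + 1L]] <- wins |>
      mutate(cohort = dataset$cohort[i], mouse = dataset$mouse[i],
             session = dataset$session[i])
  }
  list(analysis = list_rbind(met_rows), windows = list_rbind(win_rows))
}

#' Apply ROUT outlier removal per group-session metric vector
#'
#' @param tbl Analysis table.
#' @param metric Metric column to screen.
#' @param q_percent ROUT Q (percent).
#' @return The table without flagged rows; flagged count in attribute
#'   `n_outliers`.
#' @export
screen_outliers <- function(tbl, metric = "z_mean_csus", q_percent = 1) {
  keep <- rep(TRUE, nrow(tbl))
  key <- paste(tbl$cohort, tbl$session)
  for (k in unique(key)) {
    sel <- which(key == k & !is.na(tbl[[metric]]))
    if (length(sel) >= 10L) {
      r <- rout_outliers(tbl[[metric]][sel], q_percent = q_percent)
      keep[sel[r$mask]] <- FALSE
    }
  }
  out <- tbl[keep, ]
  attr(out, "n_outliers") <- sum(!keep)
  out
}

comparison_rows <- function(comp, label) {
  om <- comp$omnibus |> mutate(test = comp$test, level = "omnibus",
                               analysis = label, .before = 1)
  rows <- list(om)
  if (!is.null(comp$contrasts)) {
    rows <- c(rows, list(
      comp$contrasts |> mutate(test = comp$test, level = "contrast",
                               analysis = label, .before = 1)
    ))
  }
  bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured experiment, builds the per-trial analysis
#' table, screens outliers (ROUT, per group x session), runs the group
#' comparisons (mixed-effects repeated measures on mean CS--US z and
#' delta-z with Sidak per-session contrasts; Welch and Mann-Whitney on the
#' Euclidean statistic; Kruskal-Wallis + Dunn on slopes; Fisher's exact on
#' goal-box departures; Gaussian GLM of mean z on trial duration and
#' velocity per cohort) and, when `out_dir` is given, writes the trial
#' table, metric table, pooled responses, statistics report, resolved
#' configuration and a log. Fully deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @return List: `analysis` (per-trial table after outlier screening),
#'   `pooled` (per cohort x session pooled responses), `comparisons`
#'   (named list of `fp_comparison` objects), `report` (flat results
#'   table), `paths` (written files).
#' @export
run_pipeline <- function(config = analysis_config(), out_dir = NULL) {
  sim <- config$simulate
  cohort_specs <- map(sim$cohorts, function(ch) {
    do.call(cohort_spec, ch)
  })
  cfg_args <- sim[setdiff(names(sim), "cohorts")]
  if (!is.null(cfg_args$trial_type_fractions)) {
    cfg_args$trial_type_fractions <- unlist(cfg_args$trial_type_fractions)
  }
  scfg <- do.call(sim_config, c(cfg_args, list(seed = config$seed)))
  dataset <- simulate_cohort(cohort_specs, scfg)
  full <- analyze_dataset_full(
    dataset,
    pre_s = config$window$pre_s, post_s = config$window$post_s,
    isi_s = config$metrics$isi_s,
    preprocess = config$preprocess
  )
  analysis <- full$analysis |>
    behavior_regressors(span = config$metrics$steptime_span,
                        squared = config$metrics$squared)
  paired <- analysis |> filter(.data$type == "paired")
  screened <- screen_outliers(paired, "z_mean_csus",
                              q_percent = config$stats$rout_q_percent)
  comparisons <- list()
  two_cohorts <- length(unique(screened$cohort)) >= 2
  if (two_cohorts) {
    comparisons$z_mean_csus <- compare_groups_repeated(screened, "z_mean_csus")
    comparisons$delta_z <- compare_groups_repeated(screened, "delta_z")
    groups <- sort(unique(screened$cohort))
    e1 <- screened$euclid_log2[screened$cohort == groups[1]]
    e2 <- screened$euclid_log2[screened$cohort == groups[2]]
    e1 <- e1[!is.na(e1)]; e2 <- e2[!is.na(e2)]
    comparisons$euclid_welch <- two_sample_test(e1, e2, "welch_t")
    comparisons$euclid_mw <- two_sample_test(e1, e2, "mann_whitney")
    comparisons$slopes <- slope_comparison(screened$slope, screened$cohort)
    dep <- table(factor(screened$left_before_cue, levels = c(TRUE, FALSE)),
                 screened$cohort)
    comparisons$departures <- departure_association(as.matrix(dep))
    comparisons$steptimes <- compare_groups_repeated(screened, "post_step_ms")
  }
  for (g in unique(screened$cohort)) {
    sub <- screened |> filter(.data$cohort == g)
    comparisons[[paste0("glm_", g)]] <-
      glm_regress(sub, "z_mean_csus", c("duration_s", "velocity"))
  }
  report <- bind_rows(imap(comparisons, comparison_rows))
  pooled_tbl <- pool_window_table(full$windows)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      metrics = file.path(out_dir, "trial_metrics.csv"),
      report = file.path(out_dir, "stats_report.csv"),
      pooled = file.path(out_dir, "pooled_responses.csv"),
      config = file.path(out_dir, "resolved_config.yaml"),
      log = file.path(out_dir, "run.log")
    )
    readr::write_csv(analysis, paths[["metrics"]])
    readr::write_csv(report, paths[["report"]])
    readr::write_csv(pooled_tbl, paths[["pooled"]])
    write_config(config, paths[["config"]])
    writeLines(c(
      sprintf("ladderfp run, seed %d", config$seed),
      sprintf("trials analyzed: %d (paired: %d; outliers removed: %d)",
              nrow(analysis), nrow(paired), attr(screened, "n_outliers")),
      sprintf("comparisons: %s", paste(names(comparisons), collapse = ", "))
    ), paths[["log"]])
  }
  list(analysis = screened, full_table = analysis, pooled = pooled_tbl,
       comparisons = comparisons, report = report, paths = paths)
}

# pooled CS-locked responses per cohort x session (paired trials)
pool_window_table <- function(windows_tbl) {
  if (is.null(windows_tbl) || !nrow(windows_tbl)) return(tibble())
  windows_tbl |>
    filter(.data$type == "paired") |>
    group_by(.data$cohort, .data$session) |>
    group_modify(function(d, key) {
      p <- pool_windows(d$window)
      as_tibble(p) |> mutate(n_trials = attr(p, "n_trials"))
    }) |>
    ungroup()
}
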