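# Group-comparison layer: ROUT outlier identification, repeated-measures
# mixed-effects contrasts with Geisser-Greenhouse correction and Sidak
# adjustment, and the two-sample / rank / exact / GLM tests used for cohort
# contrasts.

new_comparison <- function(test, omnibus, contrasts = NULL,
                           descriptives = NULL, info = list()) {
  structure(list(test = test, omnibus = omnibus, contrasts = contrasts,
                 descriptives = descriptives, info = info),
            class = "fp_comparison")
}

#' @export
print.fp_comparison <- function(x, ...) {
  cat("<fp_comparison>", x$test, "\n")
  print(x$omnibus)
  if (!is.null(x$contrasts)) {
    cat("contrasts:\n")
    print(x$contrasts)
  }
  invisible(x)
}

#' @export
tidy.fp_comparison <- function(x, ...) {
  x$contrasts %||% x$omnibus
}

#' @export
glance.fp_comparison <- function(x, ...) {
  first <- x$omnibus[1, , drop = FALSE]
  bind_cols(tibble(test = x$test), first)
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^k` for a family of `k` comparisons.
#'
#' @param p Raw p-values.
#' @param k Family size (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
sidak_adjust <- function(p, k = length(p)) {
  pmin(1, 1 - (1 - p)^k)
}

#' ROUT outlier identification
#'
#' Robust-regression-based outlier detection controlling a false-discovery
#' rate Q. A robust fit (the median for a location model; an M-estimator
#' regression when `x` is supplied) yields residuals whose robust scale is
#' the 68.27th percentile of their absolute values inflated by `n/(n - k)`.
#' Residual t-ratios are converted to two-sided p-values and the most
#' extreme points (at most 30% of the data) are tested outside-in against
#' the FDR-style thresholds `Q * i / n`.
#'
#' @param values Numeric vector (>= 10 values).
#' @param q_percent FDR rate Q in percent (1 = the conventional Q = 1%).
#' @param x Optional regressor for a robust linear fit instead of the
#'   location model.
#' @return List: `mask` (TRUE = outlier), `cleaned` (values kept), `rsdr`
#'   (robust SD of residuals), `n_flagged`.
#' @export
#' @examples
#' rout_outliers(c(rnorm(50), 25))$n_flagged
rout_outliers <- function(values, q_percent = 1, x = NULL) {
  n <- length(values)
  if (n < 10L) abort("ROUT needs at least 10 values.")
  if (is.null(x)) {
    res <- values - median(values)
    k <- 1L
  } else {
    if (length(x) != n) abort("`x` must match `values` in length.")
    fit <- MASS::rlm(values ~ x, maxit = 100)
    res <- as.numeric(resid(fit))
    k <- 2L
  }
  rsdr <- as.numeric(quantile(abs(res), 0.6827)) * n / (n - k)
  if (rsdr == 0) {
    return(list(mask = rep(FALSE, n), cleaned = values, rsdr = 0,
                n_flagged = 0L))
  }
  pvals <- 2 * pt(-abs(res) / rsdr, df = n - k)
  m <- floor(0.3 * n)
  ord <- order(pvals) # most extreme first
  cand <- ord[seq_len(max(m, 1L))]
  q <- q_percent / 100
  flag_up_to <- 0L
  for (i in seq_along(cand)) {
    if (pvals[cand[i]] <= q * i / n) flag_up_to <- i
  }
  mask <- rep(FALSE, n)
  if (flag_up_to > 0L) mask[cand[seq_len(flag_up_to)]] <- TRUE
  if (all(mask)) abort("ROUT flagged every point; input unusable.")
  list(mask = mask, cleaned = values[!mask], rsdr = rsdr,
       n_flagged = sum(mask))
}

# Geisser-Greenhouse epsilon from subject x session cell means, pooled
# within groups. C is the centering matrix over the k within-subject levels.
gg_epsilon <- function(cell_means, subject, group, session) {
  wide <- tibble(subject = subject, group = group, session = session,
                 value = cell_means) |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  mat <- as.matrix(wide[, setdiff(names(wide), c("subject", "group"))])
  k <- ncol(mat)
  centered <- do.call(rbind, lapply(split(as.data.frame(mat), wide$group),
                                    function(g) scale(as.matrix(g),
                                                      scale = FALSE)))
  if (nrow(centered) <= nrow(unique(wide["group"])) || k < 2L) return(1)
  S <- crossprod(centered) / (nrow(centered) - length(unique(wide$group)))
  C <- diag(k) - matrix(1 / k, k, k)
  M <- C %*% S %*% C
  tr <- sum(diag(M))
  tr2 <- sum(M * M)
  if (tr2 <= 0) return(1)
  eps <- tr^2 / ((k - 1) * tr2)
  min(max(eps, 1 / (k - 1)), 1)
}

#' Repeated-measures group comparison (mixed-effects)
#'
#' Fits a mixed-effects model of the metric on group, session and their
#' interaction with a random intercept per subject (trials are the repeated
#' observations), reports Satterthwaite-based omnibus F tests with a
#' Geisser-Greenhouse sphericity correction applied to the within-subject
#' terms (epsilon from the pooled covariance of subject-by-session cell
#' means), and per-session group contrasts with Sidak adjustment across
#' sessions.
#'
#' @param data Per-trial tibble.
#' @param metric Column name of the response metric.
#' @param group,session,subject Column names of the grouping factor, the
#'   within-subject session factor, and the subject id.
#' @param contrasts Compute per-session Sidak-adjusted group contrasts
#'   (skippable when only the omnibus tests are needed, e.g. in
#'   simulation loops).
#' @return An `fp_comparison` with omnibus table (`term`, `df1`, `df2`,
#'   `statistic`, `p_value`, `gg_epsilon`, `p_gg`), Sidak-adjusted
#'   per-session contrasts, and group-by-session descriptives.
#' @export
compare_groups_repeated <- function(data, metric, group = "cohort",
                                    session = "session", subject = "mouse",
                                    contrasts = TRUE) {
  d <- tibble(
    value = data[[metric]],
    group = factor(data[[group]]),
    session = factor(data[[session]]),
    subject = factor(data[[subject]])
  ) |>
    filter(!is.na(.data$value))
  if (nlevels(d$group) < 2L) abort("need >= 2 groups.")
  if (nlevels(d$session) < 2L) abort("need >= 2 sessions.")
  cells <- d |> count(.data$group, .data$session, .drop = FALSE)
  empty <- cells |> filter(.data$n == 0)
  if (nrow(empty)) {
    abort(sprintf("empty group x session cell(s): %s",
                  paste(sprintf("%s:%s", empty$group, empty$session),
                        collapse = ", ")))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ group * session + (1 | subject), data = d)
  ))
  an <- suppressWarnings(anova(fit, type = 3))
  omnibus <- tibble(
    term = rownames(an),
    df1 = an$NumDF,
    df2 = an$DenDF,
    statistic = an$`F value`,
    p_value = an$`Pr(>F)`
  )
  cm <- d |>
    group_by(.data$subject, .data$group, .data$session) |>
    summarise(value = mean(.data$value), .groups = "drop")
  eps <- gg_epsilon(cm$value, cm$subject, cm$group, cm$session)
  omnibus <- omnibus |>
    mutate(
      gg_epsilon = ifelse(grepl("session", .data$term), eps, NA_real_),
      p_gg = ifelse(
        grepl("session", .data$term),
        stats::pf(.data$statistic, eps * .data$df1, eps * .data$df2,
                  lower.tail = FALSE),
        .data$p_value
      )
    )
  ctab <- NULL
  if (contrasts) {
    emm <- suppressMessages(emmeans::emmeans(fit, ~ group | session))
    ctr <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise"),
                                 adjust = "none", infer = c(FALSE, TRUE)))
    ctab <- tibble(
      session = as.character(ctr$session),
      contrast = as.character(ctr$contrast),
      estimate = ctr$estimate,
      se = ctr$SE,
      df = ctr$df,
      statistic = ctr$t.ratio,
      p_value = ctr$p.value,
      p_adj = sidak_adjust(ctr$p.value, k = nrow(ctr)),
      adjust = "sidak"
    )
  }
  desc <- d |>
    group_by(.data$group, .data$session) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = stats::sd(.data$value), .groups = "drop")
  new_comparison("mixed_effects_repeated", omnibus, ctab, desc,
                 info = list(metric = metric, gg_epsilon = eps))
}

#' Two-sample comparison (Welch's t or Mann-Whitney)
#'
#' @param a,b Numeric samples (>= 2 values each).
#' @param method `"welch_t"` (Welch-Satterthwaite df) or `"mann_whitney"`
#'   (exact two-sided p when sample sizes permit and there are no ties).
#' @return An `fp_comparison`.
#' @export
#' @examples
#' tidy(two_sample_test(rnorm(10), rnorm(10, 2), "welch_t"))
two_sample_test <- function(a, b, method = c("welch_t", "mann_whitney")) {
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs >= 2 values.")
  method <- match.arg(method)
  if (method == "welch_t") {
    ht <- t.test(a, b, var.equal = FALSE)
    omnibus <- tibble(term = "welch_t", statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p_value = ht$p.value,
                      estimate = unname(ht$estimate[1] - ht$estimate[2]))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    omnibus <- tibble(term = "mann_whitney_u", statistic = unname(ht$statistic),
                      df = NA_real_, p_value = ht$p.value,
                      estimate = median(a) - median(b))
  }
  desc <- tibble(group = c("a", "b"), n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)))
  new_comparison(method, omnibus, descriptives = desc)
}

#' Compare slopes across groups (Kruskal-Wallis + Dunn)
#'
#' Kruskal-Wallis omnibus rank test followed by Dunn's pairwise z
#' comparisons (tie-corrected) with Sidak family adjustment.
#'
#' @param values Numeric vector of slopes.
#' @param group Grouping vector (>= 2 groups, each of size >= 2).
#' @return An `fp_comparison` with the H statistic and pairwise contrasts.
#' @export
slope_comparison <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) abort("need >= 2 groups.")
  sizes <- table(group)
  if (any(sizes < 2L)) {
    abort(sprintf("group(s) with < 2 values: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  kw <- kruskal.test(values, group)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v <- n * (n + 1) / 12 - tie_term
  combs <- utils::combn(levels(group), 2)
  rows <- map(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    z <- (rbar[[g1]] - rbar[[g2]]) /
      sqrt(v * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    tibble(contrast = paste(g1, "-", g2), statistic = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  contrasts <- list_rbind(rows) |>
    mutate(p_adj = sidak_adjust(.data$p_value, k = dplyr::n()),
           adjust = "sidak")
  omnibus <- tibble(term = "kruskal_wallis",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
  grp_mean <- as.numeric(tapply(values, group, mean))
  grp_sd <- as.numeric(tapply(values, group, sd))
  desc <- tibble(group = levels(group), n = as.integer(sizes),
                 mean = grp_mean, sd = grp_sd)
  new_comparison("kruskal_wallis_dunn", omnibus, contrasts, desc)
}

#' Goal-box departure association (Fisher's exact test)
#'
#' Two-sided Fisher's exact test on a 2x2 contingency table of
#' before-/after-cue departures by group, from the hypergeometric
#' distribution.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return An `fp_comparison`.
#' @export
#' @examples
#' glance(departure_association(matrix(c(5, 0, 0, 5), 2)))
departure_association <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) abort("`counts` must be a 2x2 table.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  ht <- fisher.test(counts)
  omnibus <- tibble(term = "fisher_exact", statistic = unname(ht$estimate),
                    df = NA_real_, p_value = ht$p.value)
  new_comparison("fisher_exact", omnibus,
                 info = list(counts = counts))
}

#' Gaussian GLM regression of a metric on behavioral predictors
#'
#' Identity-link Gaussian GLM (equivalent to OLS) of, e.g., mean z in the
#' CS--US window on trial duration or velocity; reports coefficients with
#' p-values and R-squared.
#'
#' @param data Tibble with the response and predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return An `fp_comparison`; `$contrasts` holds the coefficient table and
#'   `$info$fitted` the fitted values.
#' @export
glm_regress <- function(data, response, predictors) {
  d <- data[, c(response, predictors)]
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3L) abort("regression needs >= 3 complete rows.")
  f <- stats::reformulate(predictors, response)
  X <- stats::model.matrix(f, data = d)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design matrix.")
  fit <- glm(f, data = d, family = gaussian())
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- tibble(term = rownames(co), estimate = unname(co[, 1]),
                  se = unname(co[, 2]), statistic = unname(co[, 3]),
                  p_value = unname(co[, 4]))
  r2 <- 1 - fit$deviance / fit$null.deviance
  omnibus <- tibble(term = "model", statistic = NA_real_, df = fit$df.residual,
                    p_value = coefs$p_value[min(2, nrow(coefs))],
                    r_squared = r2, n = nrow(d))
  new_comparison("glm_gaussian", omnibus, coefs,
                 info = list(formula = deparse(f), r_squared = r2,
                             fitted = as.numeric(fitted(fit))))
}
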