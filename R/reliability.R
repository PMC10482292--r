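#' Intraclass correlation of a run-level measure (absolute agreement)
#'
#' Decomposes a participant-by-run measure into between-participant and
#' within-participant (run-to-run) variance with a random-intercept model
#' and returns `ICC = var_between / (var_between + var_within)` — the
#' one-way random-effects, absolute-agreement intraclass correlation.
#' Estimation is by REML (lme4) or by the method-of-moments one-way ANOVA
#' estimator; on balanced tables the two agree.
#'
#' @param table Tibble with columns `participant_id`, `run`, and the
#'   measure; `(participant_id, run)` pairs must be unique.
#' @param measure Name of the measure column.
#' @param method `"reml"` (default) or `"anova"` (method of moments with
#'   negative between-variance truncated at 0).
#' @return An `icc_result`: list with `icc`, `var_between`, `var_within`,
#'   `conditional`, `measure`, `method`.
#' @export
#' @examples
#' tab <- tibble::tibble(participant_id = rep(c("a", "b", "c"), each = 3),
#'                       run = rep(1:3, 3),
#'                       y = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
#' icc_absolute(tab, "y")$icc
icc_absolute <- function(table, measure, method = c("reml", "anova")) {
  method <- match.arg(method)
  d <- prepare_icc_table(table, measure)
  vc <- icc_components(d, method, run_adjust = FALSE)
  new_icc_result(vc, conditional = FALSE, measure = measure, method = method)
}

#' Conditional intraclass correlation (run trend removed)
#'
#' As [icc_absolute()], but first removes a systematic practice effect — a
#' fixed effect of `log(run)` shared by all participants — so the
#' within-participant variance no longer absorbs group-level drift across
#' runs.
#'
#' @inheritParams icc_absolute
#' @return An `icc_result` with `conditional = TRUE`; the estimated
#'   `log(run)` slope is stored as `run_slope`.
#' @export
icc_conditional <- function(table, measure, method = c("reml", "anova")) {
  method <- match.arg(method)
  d <- prepare_icc_table(table, measure)
  vc <- icc_components(d, method, run_adjust = TRUE)
  new_icc_result(vc, conditional = TRUE, measure = measure, method = method)
}

prepare_icc_table <- function(table, measure) {
  assert_columns(table, c("participant_id", "run", measure), "table")
  d <- tibble::tibble(pid = factor(table$participant_id),
                      run = as.numeric(table$run),
                      y = as.numeric(table[[measure]]))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (anyDuplicated(paste(d$pid, d$run))) {
    stop("(participant_id, run) pairs must be unique", call. = FALSE)
  }
  n_per <- table(d$pid)
  if (sum(n_per >= 2) < 2) {
    stop("need at least 2 participants with at least 2 runs each",
         call. = FALSE)
  }
  if (var(d$y) == 0) {
    stop("measure is constant; ICC undefined", call. = FALSE)
  }
  droplevels(d)
}

icc_components <- function(d, method, run_adjust) {
  slope <- NA_real_
  if (method == "anova") {
    if (run_adjust) {
      fit <- stats::lm(y ~ log(run), data = d)
      slope <- unname(stats::coef(fit)[2])
      d$y <- stats::residuals(fit)
    }
    k <- nlevels(d$pid)
    n_i <- as.numeric(table(d$pid))
    N <- sum(n_i)
    grand <- mean(d$y)
    m_i <- tapply(d$y, d$pid, mean)
    ssb <- sum(n_i * (m_i - grand)^2)
    ssw <- sum((d$y - m_i[d$pid])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (N - k)
    n0 <- (N - sum(n_i^2) / N) / (k - 1)  # balanced: n0 = runs per participant
    var_b <- max(0, (msb - msw) / n0)
    var_w <- msw
  } else {
    # all-constant-within groups break the REML fit; the decomposition is
    # then trivial
    within_var <- tapply(d$y, d$pid, var)
    if (all(within_var[!is.na(within_var)] == 0) && !run_adjust) {
      return(list(var_between = var(tapply(d$y, d$pid, mean)),
                  var_within = 0, run_slope = NA_real_))
    }
    form <- if (run_adjust) y ~ log(run) + (1 | pid) else y ~ 1 + (1 | pid)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_b <- vc$vcov[vc$grp == "pid"]
    var_w <- vc$vcov[vc$grp == "Residual"]
    if (run_adjust) slope <- unname(lme4::fixef(fit)["log(run)"])
  }
  list(var_between = var_b, var_within = var_w, run_slope = slope)
}

new_icc_result <- function(vc, conditional, measure, method) {
  structure(list(icc = vc$var_between / (vc$var_between + vc$var_within),
                 var_between = vc$var_between,
                 var_within = vc$var_within,
                 run_slope = vc$run_slope,
                 conditional = conditional,
                 measure = measure,
                 method = method),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s ICC(%s) = %.3f [between %.4g, within %.4g]\n",
              if (x$conditional) "conditional" else "unconditional",
              x$measure, x$icc, x$var_between, x$var_within))
  invisible(x)
}

#' Classify a correlation magnitude
#'
#' Standard interpretive labels for test-retest correlation coefficients:
#' magnitudes below .35 are "low", between .36 and .67 "modest", and above
#' .67 "high". The unassigned gap `[.35, .36)` maps to "low". Vectorized;
#' `NA` passes through.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of `"low"`, `"modest"`, `"high"`.
#' @export
#' @examples
#' classify_correlation(c(0.3, 0.5, 0.7))
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  a <- abs(r)
  out <- ifelse(a > 0.67, "high", ifelse(a >= 0.36, "modest", "low"))
  out[is.na(r)] <- NA_character_
  out
}

#' Leave-run-out test-retest curve
#'
#' For every run `k`, correlates (Spearman, average ranks on ties) the
#' run-`k` value across participants with each participant's mean over all
#' their other runs. Runs observed in fewer than `min_n` participants with
#' at least one other run are reported as missing.
#'
#' @inheritParams icc_absolute
#' @param min_n Minimum complete participant pairs per run (default 3).
#' @return A tibble with `run`, `spearman_r`, `n`, `taylor_class`.
#' @export
leave_run_out_curve <- function(table, measure, min_n = 3) {
  assert_columns(table, c("participant_id", "run", measure), "table")
  d <- tibble::tibble(pid = as.character(table$participant_id),
                      run = table$run,
                      y = as.numeric(table[[measure]]))
  d <- d[is.finite(d$y), , drop = FALSE]
  runs <- sort(unique(d$run))
  if (length(runs) < 3) {
    stop("need at least 3 distinct runs for a leave-run-out curve",
         call. = FALSE)
  }
  purrr::map_dfr(runs, function(k) {
    held <- d[d$run == k, c("pid", "y")]
    rest <- d[d$run != k, , drop = FALSE]
    others <- tapply(rest$y, rest$pid, mean)
    m <- merge(held, data.frame(pid = names(others), other = as.numeric(others)),
               by = "pid")
    n <- nrow(m)
    r <- if (n >= min_n) cor(m$y, m$other, method = "spearman") else NA_real_
    tibble::tibble(run = k, spearman_r = r, n = n,
                   taylor_class = classify_correlation(r))
  })
}

#' Practice-trend mixed model on a run-level measure
#'
#' Fits `measure ~ log(run)` with a participant-level random intercept and
#' random `log(run)` slope, returning the fixed slope with an approximate
#' test. If the full random structure fails to converge (or is singular),
#' the model falls back to a random intercept only and flags it. The
#' p-value uses a normal approximation of the t statistic by default;
#' `method = "satterthwaite"` uses lmerTest's degrees-of-freedom correction.
#'
#' @inheritParams icc_absolute
#' @param method `"normal"` (default) or `"satterthwaite"`.
#' @return A `trend_result`: list with `slope`, `se`, `statistic`,
#'   `p_value`, `fallback`, `n_participants`, and `var_random` (random-effect
#'   variance estimates).
#' @export
run_trend <- function(table, measure, method = c("normal", "satterthwaite")) {
  method <- match.arg(method)
  assert_columns(table, c("participant_id", "run", measure), "table")
  d <- tibble::tibble(pid = factor(table$participant_id),
                      lrun = log(as.numeric(table$run)),
                      y = as.numeric(table[[measure]]))
  d <- d[is.finite(d$y), , drop = FALSE]
  counts <- table(d$pid)
  if (any(counts < 2)) {
    warning(sprintf("dropping %d participant(s) with fewer than 2 runs",
                    sum(counts < 2)))
    d <- droplevels(d[d$pid %in% names(counts)[counts >= 2], , drop = FALSE])
  }
  if (nlevels(d$pid) < 3) {
    stop("need at least 3 participants with 2+ runs", call. = FALSE)
  }
  if (var(d$y) == 0) {
    return(structure(list(slope = 0, se = 0, statistic = NA_real_,
                          p_value = NA_real_, fallback = FALSE,
                          n_participants = nlevels(d$pid),
                          var_random = NULL, measure = measure),
                     class = "trend_result"))
  }
  fit_lmm <- function(form) {
    if (method == "satterthwaite" &&
        requireNamespace("lmerTest", quietly = TRUE)) {
      lmerTest::lmer(form, data = d, REML = TRUE)
    } else {
      lme4::lmer(form, data = d, REML = TRUE)
    }
  }
  fallback <- FALSE
  fit <- tryCatch(
    suppressMessages(suppressWarnings(fit_lmm(y ~ lrun + (1 + lrun | pid)))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    fallback <- TRUE
    fit <- suppressMessages(suppressWarnings(fit_lmm(y ~ lrun + (1 | pid))))
  }
  sm <- summary(fit)$coefficients
  slope <- sm["lrun", "Estimate"]
  se <- sm["lrun", "Std. Error"]
  tval <- sm["lrun", "t value"]
  p <- if (method == "satterthwaite" && "Pr(>|t|)" %in% colnames(sm)) {
    sm["lrun", "Pr(>|t|)"]
  } else {
    2 * pnorm(-abs(tval))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(slope = slope, se = se, statistic = tval, p_value = p,
                 fallback = fallback, n_participants = nlevels(d$pid),
                 var_random = tibble::as_tibble(vc), measure = measure),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s ~ log(run): b = %.4f (SE %.4f), t = %.2f, p = %.3g%s\n",
              x$measure %||% "y", x$slope, x$se,
              x$statistic %||% NA, x$p_value %||% NA,
              if (x$fallback) " [random-intercept fallback]" else ""))
  invisible(x)
}

#' Correlations between model parameters and task performance
#'
#' Pairwise Pearson correlations, across runs, between fitted parameters
#' and the mean points earned per trial (positive correlations mean higher
#' parameter values go with better performance).
#'
#' @param table Run-level tibble.
#' @param measures Columns to correlate; defaults to the four parameters
#'   plus `mean_reward` where present.
#' @return A correlation matrix.
#' @export
performance_correlations <- function(table, measures = NULL) {
  if (is.null(measures)) {
    measures <- intersect(c("alpha_win", "alpha_loss", "beta", "lambda",
                            "lam", "log_likelihood", "mean_reward"),
                          names(table))
  }
  assert_columns(table, measures, "table")
  cor(as.matrix(table[measures]), use = "pairwise.complete.obs")
}

#' Descriptive and reliability report for run-level measures
#'
#' For each measure: mean, SD, median, 10th/90th percentiles, and the
#' unconditional and conditional ICCs.
#'
#' @param table Run-level tibble with `participant_id`, `run`, and the
#'   measures.
#' @param measures Character vector of measure columns.
#' @param method ICC estimation method, see [icc_absolute()].
#' @return A tibble with one row per measure.
#' @export
reliability_report <- function(table, measures, method = "reml") {
  purrr::map_dfr(measures, function(m) {
    y <- as.numeric(table[[m]])
    y <- y[is.finite(y)]
    tibble::tibble(
      measure = m,
      mean = mean(y), sd = sd(y), median = median(y),
      p10 = unname(quantile(y, 0.10)), p90 = unname(quantile(y, 0.90)),
      icc_unc = icc_absolute(table, m, method)$icc,
      icc_cond = icc_conditional(table, m, method)$icc)
  })
}
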