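#' Configure the per-run maximum-likelihood fit
#'
#' The likelihood surface is multi-modal in the two learning rates, so the
#' fit runs `n_starts` local constrained optimizations (L-BFGS-B) from
#' starting points drawn uniformly inside the parameter box and keeps the
#' best. The box is `[0, 1]` for both learning rates and `lam`, and
#' `[0, beta_max]` for reward sensitivity (a finite stand-in for an
#' unbounded upper limit; the default 20 is non-binding for realistic
#' behavior).
#'
#' @param n_starts Number of random starting points (default 10).
#' @param beta_max Upper bound of the reward-sensitivity box (default 20).
#' @param rescale_magnitudes Passed through to [run_log_likelihood()].
#' @param maxit Maximum optimizer iterations per start.
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_starts = 10, beta_max = 20,
                       rescale_magnitudes = TRUE, maxit = 500) {
  if (!is_count(n_starts)) stop("`n_starts` must be >= 1", call. = FALSE)
  if (!is.numeric(beta_max) || beta_max <= 0) {
    stop("`beta_max` must be positive", call. = FALSE)
  }
  structure(list(n_starts = as.integer(n_starts),
                 beta_max = beta_max,
                 rescale_magnitudes = isTRUE(rescale_magnitudes),
                 maxit = as.integer(maxit),
                 lower = c(alpha_win = 0, alpha_loss = 0, beta = 0, lam = 0),
                 upper = c(alpha_win = 1, alpha_loss = 1, beta = beta_max,
                           lam = 1)),
            class = "fit_config")
}

#' Fit the four-parameter model to one run
#'
#' Maximizes [run_log_likelihood()] over the parameter box by multi-start
#' L-BFGS-B. Deterministic given `data`, `config`, and `seed`. If every
#' start fails, the best starting point itself is returned with
#' `converged = FALSE`; the function never errors on optimizer failure.
#'
#' @param data Choice data with columns `choice`, `r_A`, `f_A`, `f_B`.
#' @param config A [fit_config()].
#' @param seed Optional integer seed governing the starting points.
#' @return A `fit_result`: list with `params` ([model_params()]),
#'   `log_likelihood`, `converged`, `n_starts_used`, and `at_bound`
#'   (named logical flags for parameters on the box boundary).
#' @export
#' @examples
#' stim <- generate_run_stimuli(task_config(), seed = 1)
#' cd <- simulate_run(model_params(0.7, 0.3, 5, 0.9), stim, seed = 2)
#' fit_run(cd, seed = 3)
fit_run <- function(data, config = fit_config(), seed = NULL) {
  assert_columns(data, c("choice", "r_A", "f_A", "f_B"), "choice data")
  if (nrow(data) < 2) stop("need at least 2 trials to fit", call. = FALSE)
  choice_a <- as.integer(data$choice == "A")
  r_a <- as.integer(data$r_A)
  f_a <- as.numeric(data$f_A)
  f_b <- as.numeric(data$f_B)
  scale <- if (config$rescale_magnitudes) 1 / 100 else 1
  nll <- function(par) {
    -cpp_run_loglik(choice_a, r_a, f_a, f_b,
                    par[1], par[2], par[3], par[4], scale, 1e-12)
  }
  lower <- unname(config$lower)
  upper <- unname(config$upper)
  starts <- with_seed(seed, {
    matrix(runif(4L * config$n_starts), ncol = 4L) %*% diag(upper - lower) +
      matrix(lower, config$n_starts, 4L, byrow = TRUE)
  })
  best <- NULL
  best_val <- Inf
  converged <- FALSE
  for (i in seq_len(config$n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = config$maxit)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$value < best_val) {
      best <- res
      best_val <- res$value
      converged <- res$convergence == 0
    }
  }
  if (is.null(best)) {
    # all starts failed: report the best raw starting point, flagged
    vals <- apply(starts, 1L, nll)
    i <- which.min(vals)
    best <- list(par = starts[i, ], value = vals[i])
    best_val <- vals[i]
    converged <- FALSE
  }
  par <- pmin(pmax(best$par, lower), upper)
  tol <- 1e-6
  structure(
    list(params = model_params(par[1], par[2], par[3], par[4]),
         log_likelihood = -best_val,
         converged = converged,
         n_starts_used = config$n_starts,
         at_bound = setNames(abs(par - lower) < tol | abs(par - upper) < tol,
                             names(config$lower))),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> logLik = %.3f (%s)\n", x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Derive the random-choice quality-control threshold
#'
#' Simulates `n_sims` runs in which every choice is uniformly random on
#' freshly generated stimuli, fits each run with the full model, and returns
#' the 95th percentile of the fitted log-likelihoods. Runs whose fitted
#' log-likelihood falls below this threshold are improbable to arise from
#' anything better than random responding.
#'
#' @param task_config A [task_config()].
#' @param fit_config A [fit_config()].
#' @param n_sims Number of simulated random-choice runs (>= 100; 1000 is
#'   adequate for testing, 10000 for production use).
#' @param seed Optional integer seed.
#' @param prob Percentile to return (default 0.95).
#' @return The threshold (numeric scalar) with the simulated fitted
#'   log-likelihoods attached as attribute `"log_likelihoods"`.
#' @export
derive_random_choice_threshold <- function(task_config = banditrl::task_config(),
                                           fit_config = banditrl::fit_config(),
                                           n_sims = 1000, seed = NULL,
                                           prob = 0.95) {
  if (!is_count(n_sims) || n_sims < 100) {
    stop("`n_sims` must be at least 100", call. = FALSE)
  }
  with_seed(seed, {
    lls <- vapply(seq_len(n_sims), function(i) {
      stim <- generate_run_stimuli(task_config)
      choices <- sample(c("A", "B"), task_config$n_trials, replace = TRUE)
      out <- realize_outcomes(stim, choices)
      dat <- tibble::tibble(choice = choices, r_A = out$r_A,
                            f_A = stim$f_A, f_B = stim$f_B)
      fit_run(dat, fit_config)$log_likelihood
    }, numeric(1))
    thr <- unname(quantile(lls, prob))
    attr(thr, "log_likelihoods") <- lls
    thr
  })
}

#' Quality-control filter on fitted runs
#'
#' Drops runs whose fitted log-likelihood is strictly below `threshold`
#' (runs exactly at the threshold are kept), then drops participants left
#' with fewer than `min_runs` surviving runs.
#'
#' @param fits Tibble with columns `participant_id`, `run`,
#'   `log_likelihood`.
#' @param threshold Log-likelihood cutoff (e.g. from
#'   [derive_random_choice_threshold()]).
#' @param min_runs Minimum surviving runs per participant (default 10).
#' @return A `qc_report`: list with `threshold`, `kept` and `excluded_runs`
#'   (participant/run tibbles), `excluded_participants`,
#'   `exclusion_fraction` (fraction of all runs not kept), and `table`, the
#'   input annotated with `excluded_qc` and `exclusion_reason`.
#' @export
qc_filter <- function(fits, threshold, min_runs = 10) {
  assert_columns(fits, c("participant_id", "run", "log_likelihood"), "fits")
  if (nrow(fits) == 0) stop("`fits` is empty", call. = FALSE)
  threshold <- as.numeric(threshold)
  tab <- dplyr::mutate(fits, .below = .data$log_likelihood < threshold)
  surv <- dplyr::summarise(dplyr::group_by(tab, .data$participant_id),
                           n_surviving = sum(!.data$.below), .groups = "drop")
  few <- surv$participant_id[surv$n_surviving < min_runs]
  tab <- dplyr::mutate(
    tab,
    exclusion_reason = dplyr::case_when(
      .data$.below ~ "log_likelihood_below_threshold",
      .data$participant_id %in% few ~ "participant_below_min_runs",
      TRUE ~ NA_character_),
    excluded_qc = !is.na(.data$exclusion_reason))
  tab$.below <- NULL
  kept <- dplyr::select(dplyr::filter(tab, !.data$excluded_qc),
                        "participant_id", "run")
  excl <- dplyr::select(dplyr::filter(tab, .data$excluded_qc),
                        "participant_id", "run", "exclusion_reason")
  structure(list(threshold = threshold,
                 kept = kept,
                 excluded_runs = excl,
                 excluded_participants = as.character(few),
                 exclusion_fraction = nrow(excl) / nrow(tab),
                 min_runs = min_runs,
                 table = tab),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> threshold = %.3f | kept %d / %d runs (%.1f%% excluded) | %d participant(s) dropped (< %d runs)\n",
              x$threshold, nrow(x$kept), nrow(x$table),
              100 * x$exclusion_fraction, length(x$excluded_participants),
              x$min_runs))
  invisible(x)
}

#' Filter trials with extreme response times
#'
#' Keeps trials with `lower < rt_ms < upper` (defaults 50 and 10000 ms,
#' strict on both sides) and records the fraction removed as attribute
#' `"fraction_removed"`.
#'
#' @param trials Tibble with an `rt_ms` column.
#' @param lower,upper Bounds in milliseconds.
#' @return The filtered tibble.
#' @export
rt_filter <- function(trials, lower = 50, upper = 10000) {
  assert_columns(trials, "rt_ms", "trials")
  keep <- !is.na(trials$rt_ms) & trials$rt_ms > lower & trials$rt_ms < upper
  out <- trials[keep, , drop = FALSE]
  attr(out, "fraction_removed") <- 1 - sum(keep) / nrow(trials)
  out
}

#' Draw parameter sets from the reference population moments
#'
#' Truncated-normal draws per parameter, by default matching the reference
#' sample's fitted-parameter means and SDs: alpha_win 0.68 +/- 0.28 and
#' alpha_loss 0.34 +/- 0.23 on `[0, 1]`, beta 4.98 +/- 2.37 on
#' `[0, beta_max]`, lam 0.92 +/- 0.12 on `[0, 1]`.
#'
#' @param n Number of parameter sets.
#' @param seed Optional integer seed.
#' @param means,sds Named numeric vectors over
#'   `alpha_win, alpha_loss, beta, lam`.
#' @param beta_max Upper truncation bound for beta (default 20).
#' @return A tibble with one row per set and the four parameter columns.
#' @export
sample_param_sets <- function(n, seed = NULL,
                              means = c(alpha_win = 0.68, alpha_loss = 0.34,
                                        beta = 4.98, lam = 0.92),
                              sds = c(alpha_win = 0.28, alpha_loss = 0.23,
                                      beta = 2.37, lam = 0.12),
                              beta_max = 20) {
  with_seed(seed, {
    tibble::tibble(
      alpha_win = rtruncnorm(n, means[["alpha_win"]], sds[["alpha_win"]], 0, 1),
      alpha_loss = rtruncnorm(n, means[["alpha_loss"]], sds[["alpha_loss"]], 0, 1),
      beta = rtruncnorm(n, means[["beta"]], sds[["beta"]], 0, beta_max),
      lam = rtruncnorm(n, means[["lam"]], sds[["lam"]], 0, 1)
    )
  })
}

#' Parameter-recovery simulation
#'
#' For each parameter set, simulates one run on freshly generated stimuli
#' and refits it with the same estimation procedure, then correlates
#' generating and recovered values per parameter. This verifies that the
#' fitted parameters actually capture the behavior that produced the data.
#'
#' @param param_sets Tibble with columns `alpha_win`, `alpha_loss`, `beta`,
#'   `lam` (>= 50 rows), e.g. from [sample_param_sets()].
#' @param task_config A [task_config()].
#' @param fit_config A [fit_config()].
#' @param seed Optional integer seed.
#' @return A list with `correlations` (tibble: `parameter`, `pearson`,
#'   `spearman`) and `fits`, the generating values alongside the recovered
#'   ones (`.hat` suffix) and each run's fitted log-likelihood.
#' @export
parameter_recovery <- function(param_sets,
                               task_config = banditrl::task_config(),
                               fit_config = banditrl::fit_config(),
                               seed = NULL) {
  assert_columns(param_sets, c("alpha_win", "alpha_loss", "beta", "lam"),
                 "param_sets")
  if (nrow(param_sets) < 50) {
    stop("parameter recovery needs at least 50 parameter sets", call. = FALSE)
  }
  with_seed(seed, {
    rec <- purrr::map_dfr(seq_len(nrow(param_sets)), function(i) {
      gen <- model_params(param_sets$alpha_win[i], param_sets$alpha_loss[i],
                          param_sets$beta[i], param_sets$lam[i])
      stim <- generate_run_stimuli(task_config)
      cd <- simulate_run(gen, stim,
                         rescale_magnitudes = fit_config$rescale_magnitudes)
      fit <- fit_run(cd, fit_config)
      tibble::tibble(alpha_win_hat = fit$params$alpha_win,
                     alpha_loss_hat = fit$params$alpha_loss,
                     beta_hat = fit$params$beta,
                     lam_hat = fit$params$lam,
                     log_likelihood = fit$log_likelihood,
                     converged = fit$converged)
    })
    pars <- c("alpha_win", "alpha_loss", "beta", "lam")
    safe_cor <- function(x, y, ...) {
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)  # undefined, not an error
      cor(x, y, ...)
    }
    correlations <- purrr::map_dfr(pars, function(p) {
      tibble::tibble(
        parameter = p,
        pearson = safe_cor(param_sets[[p]], rec[[paste0(p, "_hat")]]),
        spearman = safe_cor(param_sets[[p]], rec[[paste0(p, "_hat")]],
                            method = "spearman"))
    })
    list(correlations = correlations,
         fits = dplyr::bind_cols(param_sets[pars], rec))
  })
}
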