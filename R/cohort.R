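#' Design a synthetic longitudinal cohort
#'
#' A cohort design fixes, for each model parameter, a population mean, a
#' between-participant SD, a within-participant (run-to-run) SD, and an
#' optional linear trend on `log(run)`; draws are truncated to the legal
#' parameter bounds. The implied intraclass correlation of a parameter's
#' true values is `sd_between^2 / (sd_between^2 + sd_within^2)`. The design
#' also covers visual-analogue-scale (0-100) momentary-state items with the
#' same between/within structure, and a lognormal response-time model with a
#' participant-level location shift and a `log(run)` speed-up.
#'
#' @param n_participants Number of participants.
#' @param runs Either a single run count per participant or a length-2 range
#'   from which each participant's run count is drawn uniformly (default
#'   `c(10, 31)`, emulating attrition between a 10-run inclusion floor and a
#'   31-run maximum).
#' @param params Tibble with columns `parameter`
#'   (`alpha_win`, `alpha_loss`, `beta`, `lam`), `mean`, `sd_between`,
#'   `sd_within`, `slope`, `lower`, `upper`. Defaults to
#'   [table1_param_design()].
#' @param ema Tibble with columns `item`, `mean`, `sd_between`, `sd_within`
#'   (VAS scale 0-100), or `NULL`. Defaults to [table1_ema_design()].
#' @param rt List with `meanlog`, `sdlog` (trial-level lognormal of RT in
#'   ms), `sd_between` (participant shift of `meanlog`), `slope` (change of
#'   `meanlog` per `log(run)`).
#' @param early_noise_boost,early_noise_decay Optional extra run-to-run
#'   noise in early runs: the within-SD at run `k` is multiplied by
#'   `1 + boost * exp(-(k - 1) / decay)`. Default boost 0 (stationary).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_participants = 400,
                          runs = c(10, 31),
                          params = table1_param_design(),
                          ema = table1_ema_design(),
                          rt = list(meanlog = log(800), sdlog = 0.5,
                                    sd_between = 0.3, slope = -0.05),
                          early_noise_boost = 0,
                          early_noise_decay = 3) {
  if (length(runs) == 1L) runs <- c(runs, runs)
  design <- structure(list(n_participants = as.integer(n_participants),
                           runs = as.integer(runs),
                           params = tibble::as_tibble(params),
                           ema = if (is.null(ema)) NULL else tibble::as_tibble(ema),
                           rt = rt,
                           early_noise_boost = early_noise_boost,
                           early_noise_decay = early_noise_decay),
                      class = "cohort_design")
  validate_cohort_design(design)
}

validate_cohort_design <- function(design) {
  if (!is_count(design$n_participants)) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  r <- design$runs
  if (length(r) != 2L || r[1] > r[2] || r[1] < 2) {
    stop("`runs` must be a count or range with at least 2 runs", call. = FALSE)
  }
  p <- design$params
  assert_columns(p, c("parameter", "mean", "sd_between", "sd_within",
                      "slope", "lower", "upper"), "params design")
  need <- c("alpha_win", "alpha_loss", "beta", "lam")
  if (!setequal(p$parameter, need)) {
    stop("params design must cover exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(p$sd_between < 0) || any(p$sd_within < 0)) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  if (!is.null(design$ema)) {
    assert_columns(design$ema, c("item", "mean", "sd_between", "sd_within"),
                   "ema design")
    if (any(design$ema$sd_between < 0) || any(design$ema$sd_within < 0)) {
      stop("EMA SDs must be non-negative", call. = FALSE)
    }
  }
  if (design$early_noise_boost < 0 || design$early_noise_decay <= 0) {
    stop("early-noise settings must be non-negative (decay > 0)", call. = FALSE)
  }
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d participants, %d-%d runs, %d EMA item(s)\n",
              x$n_participants, x$runs[1], x$runs[2],
              if (is.null(x$ema)) 0L else nrow(x$ema)))
  print(x$params)
  invisible(x)
}

#' Default parameter population design (reference-sample moments)
#'
#' Population means and SDs of the four fitted parameters in the reference
#' sample, with the between/within split reverse-engineered from the
#' published intraclass correlations (`sd_between = sd * sqrt(ICC)`,
#' `sd_within = sd * sqrt(1 - ICC)`): alpha_win 0.68 +/- 0.28 (ICC .23),
#' alpha_loss 0.34 +/- 0.23 (ICC .53), beta 4.98 +/- 2.37 (ICC .33),
#' lam 0.92 +/- 0.12 (ICC .40). Slopes default to 0 (no practice trend).
#'
#' @return A params-design tibble for [cohort_design()].
#' @export
table1_param_design <- function() {
  moments <- tibble::tribble(
    ~parameter,   ~mean, ~sd,   ~icc, ~lower, ~upper,
    "alpha_win",  0.68,  0.28,  0.23, 0,      1,
    "alpha_loss", 0.34,  0.23,  0.53, 0,      1,
    "beta",       4.98,  2.37,  0.33, 0,      20,
    "lam",        0.92,  0.12,  0.40, 0,      1
  )
  tibble::tibble(parameter = moments$parameter,
                 mean = moments$mean,
                 sd_between = moments$sd * sqrt(moments$icc),
                 sd_within = moments$sd * sqrt(1 - moments$icc),
                 slope = 0,
                 lower = moments$lower,
                 upper = moments$upper)
}

#' Default momentary-state item design (reference-sample moments)
#'
#' The six 0-100 VAS state items with reference means, SDs, and the
#' between/within split implied by their published ICCs.
#'
#' @return An EMA-design tibble for [cohort_design()].
#' @export
table1_ema_design <- function() {
  moments <- tibble::tribble(
    ~item,                        ~mean, ~sd,   ~icc,
    "alertness",                  56.8,  22.8,  0.30,
    "happiness",                  59.1,  23.3,  0.40,
    "sadness",                    29.3,  24.9,  0.41,
    "stress",                     31.7,  24.7,  0.46,
    "distraction_environment",    25.7,  23.4,  0.35,
    "distraction_thoughts",       30.5,  25.4,  0.52
  )
  tibble::tibble(item = moments$item,
                 mean = moments$mean,
                 sd_between = moments$sd * sqrt(moments$icc),
                 sd_within = moments$sd * sqrt(1 - moments$icc))
}

#' Default design matching the reference sample's moments
#'
#' Convenience wrapper bundling [table1_param_design()] and
#' [table1_ema_design()] into a full [cohort_design()].
#'
#' @inheritParams cohort_design
#' @return A `cohort_design`.
#' @export
#' @examples
#' d <- design_from_table1()
#' d$params
design_from_table1 <- function(n_participants = 400, runs = c(10, 31)) {
  cohort_design(n_participants = n_participants, runs = runs,
                params = table1_param_design(), ema = table1_ema_design())
}

#' Draw each participant's base model parameters
#'
#' Truncated-normal draws around the population means with the
#' between-participant SDs; draws never leave the configured bounds.
#'
#' @param design A [cohort_design()].
#' @param seed Optional integer seed.
#' @return A tibble with `participant_id` and the four parameter columns.
#' @export
sample_participant_params <- function(design, seed = NULL) {
  validate_cohort_design(design)
  with_seed(seed, {
    n <- design$n_participants
    out <- tibble::tibble(participant_id = sprintf("P%04d", seq_len(n)))
    for (i in seq_len(nrow(design$params))) {
      row <- design$params[i, ]
      out[[row$parameter]] <- rtruncnorm(n, row$mean, row$sd_between,
                                         row$lower, row$upper)
    }
    out
  })
}

#' Generate a full synthetic study
#'
#' Per participant and run, the true model parameters are the participant's
#' base values plus iid truncated-Gaussian run-to-run jitter (optionally
#' inflated in early runs) plus the designed `log(run)` trend. Gameplay is
#' then simulated trial by trial with [simulate_run()] on fresh stimuli,
#' response times are drawn from the lognormal RT model, and state items
#' from the additive between/within model (clamped to the 0-100 scale,
#' independent of gameplay).
#'
#' @param design A [cohort_design()].
#' @param seed Optional integer seed; the same seed regenerates identical
#'   tables.
#' @param simulate_gameplay If `FALSE`, only the truth and EMA tables are
#'   generated (no trial-level simulation) — sufficient and much faster for
#'   reliability studies on designed measures.
#' @param task_config A [task_config()] used for the simulated runs.
#' @return A `synthetic_cohort`: list with `trials` (trial-level table in
#'   the package CSV dialect, or `NULL`), `truth` (participant x run
#'   generating parameters, plus `mean_reward` when gameplay is simulated),
#'   `ema`, and `design`.
#' @export
#' @examples
#' coh <- generate_cohort(design_from_table1(n_participants = 3, runs = c(3, 4)),
#'                        seed = 1)
#' head(coh$truth)
generate_cohort <- function(design, seed = NULL, simulate_gameplay = TRUE,
                            task_config = banditrl::task_config()) {
  validate_cohort_design(design)
  with_seed(seed, {
    base <- sample_participant_params(design)
    n <- design$n_participants
    n_runs <- if (design$runs[1] == design$runs[2]) {
      rep(design$runs[1], n)
    } else {
      sample(seq.int(design$runs[1], design$runs[2]), n, replace = TRUE)
    }

    # truth table: per-run generating parameters
    truth <- purrr::map_dfr(seq_len(n), function(i) {
      runs <- seq_len(n_runs[i])
      noise_mult <- 1 + design$early_noise_boost *
        exp(-(runs - 1) / design$early_noise_decay)
      row <- tibble::tibble(participant_id = base$participant_id[i],
                            run = runs)
      for (j in seq_len(nrow(design$params))) {
        p <- design$params[j, ]
        val <- base[[p$parameter]][i] + p$slope * log(runs) +
          rnorm(length(runs), 0, p$sd_within) * noise_mult
        row[[p$parameter]] <- pmin(pmax(val, p$lower), p$upper)
      }
      row
    })

    # EMA table: additive between/within model, clamped to the VAS scale
    ema <- NULL
    if (!is.null(design$ema)) {
      ema <- purrr::map_dfr(seq_len(n), function(i) {
        runs <- seq_len(n_runs[i])
        row <- tibble::tibble(participant_id = base$participant_id[i],
                              run = runs)
        for (j in seq_len(nrow(design$ema))) {
          it <- design$ema[j, ]
          b_i <- rnorm(1, 0, it$sd_between)
          val <- it$mean + b_i + rnorm(length(runs), 0, it$sd_within)
          row[[it$item]] <- pmin(pmax(val, 0), 100)
        }
        row
      })
    }

    trials <- NULL
    if (simulate_gameplay) {
      rt_b <- rnorm(n, 0, design$rt$sd_between)
      names(rt_b) <- base$participant_id
      trials <- purrr::map_dfr(seq_len(nrow(truth)), function(k) {
        tr <- truth[k, ]
        pars <- model_params(tr$alpha_win, tr$alpha_loss, tr$beta, tr$lam)
        stim <- generate_run_stimuli(task_config)
        cd <- simulate_run(pars, stim)
        meanlog <- design$rt$meanlog + rt_b[[tr$participant_id]] +
          design$rt$slope * log(tr$run)
        tibble::tibble(participant_id = tr$participant_id,
                       run = tr$run,
                       trial = cd$trial,
                       p_win_A = stim$p_win_A,
                       f_A = cd$f_A, f_B = cd$f_B,
                       choice = cd$choice,
                       won = cd$won,
                       points_delta = cd$points_delta,
                       rt_ms = rlnorm(nrow(cd), meanlog, design$rt$sdlog))
      })
      perf <- dplyr::summarise(
        dplyr::group_by(trials, .data$participant_id, .data$run),
        mean_reward = mean(.data$points_delta),
        median_rt = median(.data$rt_ms), .groups = "drop")
      truth <- dplyr::left_join(truth, perf,
                                by = c("participant_id", "run"))
    }
    structure(list(trials = trials, truth = truth, ema = ema,
                   design = design, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, %d runs%s\n",
              x$design$n_participants, nrow(x$truth),
              if (is.null(x$trials)) " (no gameplay simulated)"
              else sprintf(", %d trials", nrow(x$trials))))
  invisible(x)
}
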