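# File formats and the pipeline entry points binding the stages together.
# CSV dialect: comma-separated, UTF-8, mandatory header, runs and trials
# 1-based, missing values as empty fields.

trial_cols <- function() {
  readr::cols(participant_id = readr::col_character(),
              run = readr::col_integer(),
              trial = readr::col_integer(),
              p_win_A = readr::col_double(),
              f_A = readr::col_integer(),
              f_B = readr::col_integer(),
              choice = readr::col_character(),
              won = readr::col_logical(),
              points_delta = readr::col_integer(),
              rt_ms = readr::col_double(),
              .default = readr::col_guess())
}

#' Read / write trial tables in the package CSV dialect
#'
#' Long-format per-trial tables with columns `participant_id`, `run`,
#' `trial`, `p_win_A`, `f_A`, `f_B`, `choice`, `won`, `points_delta`,
#' `rt_ms` (and optionally `timestamp`). Malformed rows raise an error
#' naming the offending lines.
#'
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # parse problems are re-raised as errors below, so readr's warnings are noise
  tr <- suppressWarnings(readr::read_csv(path, col_types = trial_cols(),
                                         progress = FALSE,
                                         show_col_types = FALSE))
  probs <- readr::problems(tr)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed rows in %s (lines %s)", path,
                 paste(unique(probs$row), collapse = ", ")), call. = FALSE)
  }
  if (nrow(tr) == 0) stop("no trial rows in ", path, call. = FALSE)
  assert_columns(tr, c("participant_id", "run", "trial", "choice"),
                 basename(path))
  tr
}

#' @param trials Trial tibble.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' Serialize / restore configuration objects as JSON
#'
#' Round-trips [task_config()], [fit_config()] and [cohort_design()]
#' objects.
#'
#' @param config Configuration object.
#' @param path File path.
#' @return `read_config()` returns the restored object.
#' @export
write_config <- function(config, path) {
  type <- class(config)[1]
  payload <- unclass(config)
  if (type == "cohort_design") {
    payload$params <- as.data.frame(payload$params)
    if (!is.null(payload$ema)) payload$ema <- as.data.frame(payload$ema)
  }
  jsonlite::write_json(list(type = type, config = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  switch(obj$type,
         task_config = task_config(cfg$n_trials, cfg$walk_sd, cfg$walk_bounds,
                                   cfg$init_good, cfg$init_bad,
                                   cfg$magnitude_low, cfg$magnitude_high),
         fit_config = fit_config(cfg$n_starts, cfg$beta_max,
                                 cfg$rescale_magnitudes, cfg$maxit),
         cohort_design = cohort_design(cfg$n_participants, cfg$runs,
                                       tibble::as_tibble(cfg$params),
                                       if (is.null(cfg$ema)) NULL
                                       else tibble::as_tibble(cfg$ema),
                                       cfg$rt, cfg$early_noise_boost,
                                       cfg$early_noise_decay),
         stop("unknown config type: ", obj$type, call. = FALSE))
}

#' Simulate a cohort and materialize it on disk
#'
#' Generates a [generate_cohort()] cohort and writes `trials.csv`,
#' `truth.csv`, `ema.csv`, the design JSON, and a `manifest.json` recording
#' the seed, a design hash, and row counts. Outputs are byte-identical for
#' identical design + seed.
#'
#' @param design A [cohort_design()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param simulate_gameplay Passed to [generate_cohort()].
#' @return The cohort, invisibly, with file paths in attribute `"paths"`.
#' @export
run_simulate <- function(design, outdir, seed = 1, simulate_gameplay = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  coh <- generate_cohort(design, seed = seed,
                         simulate_gameplay = simulate_gameplay)
  paths <- list()
  if (!is.null(coh$trials)) {
    paths$trials <- file.path(outdir, "trials.csv")
    write_trials(coh$trials, paths$trials)
  }
  paths$truth <- file.path(outdir, "truth.csv")
  readr::write_csv(coh$truth, paths$truth, na = "")
  if (!is.null(coh$ema)) {
    paths$ema <- file.path(outdir, "ema.csv")
    readr::write_csv(coh$ema, paths$ema, na = "")
  }
  paths$design <- file.path(outdir, "design.json")
  write_config(design, paths$design)
  manifest <- list(seed = seed,
                   design_hash = rlang::hash(unclass(design)),
                   n_participants = design$n_participants,
                   rows = list(trials = if (is.null(coh$trials)) 0L
                               else nrow(coh$trials),
                               truth = nrow(coh$truth),
                               ema = if (is.null(coh$ema)) 0L
                               else nrow(coh$ema)))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(coh, "paths") <- paths
  invisible(coh)
}

#' Fit every run in a trial table and apply quality control
#'
#' Splits the trial table by participant and run, fits each run with
#' [fit_run()], derives the random-choice threshold (unless one is
#' supplied), and annotates the results with [qc_filter()].
#'
#' @param trials Trial tibble in the package dialect, or a path to a
#'   `trials.csv`.
#' @param fit_config A [fit_config()].
#' @param threshold Log-likelihood QC cutoff; `NULL` (default) derives one
#'   via [derive_random_choice_threshold()].
#' @param n_sims Simulations for threshold derivation.
#' @param min_runs Minimum surviving runs per participant (default 10).
#' @param seed Integer seed (fits and threshold derivation).
#' @param task_config Task settings used for threshold derivation; trial
#'   counts should match the data.
#' @param outdir Optional directory to write `fits.csv` into.
#' @return A list with `fits` (tibble: `participant_id`, `run`,
#'   `alpha_win`, `alpha_loss`, `beta`, `lambda`, `log_likelihood`,
#'   `converged`, `excluded_qc`), `qc` (a `qc_report`), and `threshold`.
#' @export
run_fit <- function(trials, fit_config = banditrl::fit_config(),
                    threshold = NULL, n_sims = 1000, min_runs = 10,
                    seed = 1, task_config = banditrl::task_config(),
                    outdir = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  assert_columns(trials, c("participant_id", "run", "trial", "choice",
                           "won", "f_A", "f_B"), "trials")
  # effective-option indicator reconstructed from choice + won under
  # complementary probabilities
  trials$r_A <- as.integer((trials$choice == "A") == trials$won)
  keys <- dplyr::distinct(trials, .data$participant_id, .data$run)
  fits <- purrr::map_dfr(seq_len(nrow(keys)), function(k) {
    d <- trials[trials$participant_id == keys$participant_id[k] &
                  trials$run == keys$run[k], , drop = FALSE]
    fit <- fit_run(d[order(d$trial), ], fit_config,
                   seed = (seed + 7L * k) %% .Machine$integer.max)
    tibble::tibble(participant_id = keys$participant_id[k],
                   run = keys$run[k],
                   alpha_win = fit$params$alpha_win,
                   alpha_loss = fit$params$alpha_loss,
                   beta = fit$params$beta,
                   lambda = fit$params$lam,
                   log_likelihood = fit$log_likelihood,
                   converged = fit$converged,
                   mean_reward = mean(d$points_delta))
  })
  if (is.null(threshold)) {
    threshold <- derive_random_choice_threshold(task_config, fit_config,
                                                n_sims = n_sims,
                                                seed = seed + 1L)
  }
  qc <- qc_filter(fits, threshold, min_runs = min_runs)
  fits$excluded_qc <- qc$table$excluded_qc
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(fits, file.path(outdir, "fits.csv"), na = "")
  }
  list(fits = fits, qc = qc, threshold = as.numeric(threshold))
}

#' Reliability stage: descriptives, ICCs, curves, and trends
#'
#' Runs the longitudinal psychometrics over a QC'd fit table (and,
#' optionally, a momentary-state table): the descriptive + ICC report per
#' measure, leave-run-out test-retest curves, and `log(run)` practice-trend
#' models. Participants contributing a single run are dropped with a
#' warning.
#'
#' @param fits Fit tibble from [run_fit()] (or a path to `fits.csv`); rows
#'   with `excluded_qc = TRUE` are dropped first.
#' @param ema Optional state-item tibble (`participant_id`, `run`, items).
#' @param measures Measure columns of `fits` to analyze; defaults to the
#'   four parameters plus `log_likelihood` and `mean_reward` when present.
#' @param outdir Optional directory to write `report.csv` and `curves.csv`.
#' @return A list with `report`, `curves`, and `trends` (one
#'   `trend_result` per measure).
#' @export
run_reliability <- function(fits, ema = NULL, measures = NULL,
                            outdir = NULL) {
  if (is.character(fits)) {
    fits <- readr::read_csv(fits, progress = FALSE, show_col_types = FALSE)
  }
  assert_columns(fits, c("participant_id", "run"), "fits")
  if ("excluded_qc" %in% names(fits)) {
    fits <- fits[!fits$excluded_qc, , drop = FALSE]
  }
  counts <- table(fits$participant_id)
  single <- names(counts)[counts < 2]
  if (length(single) > 0) {
    warning(sprintf("skipping %d participant(s) with a single run",
                    length(single)))
    fits <- fits[!fits$participant_id %in% single, , drop = FALSE]
  }
  if (is.null(measures)) {
    measures <- intersect(c("alpha_win", "alpha_loss", "beta", "lambda",
                            "log_likelihood", "mean_reward", "median_rt"),
                          names(fits))
  }
  assert_columns(fits, measures, "fits")
  report <- reliability_report(fits, measures)
  curves <- purrr::map_dfr(measures, function(m) {
    dplyr::bind_cols(tibble::tibble(measure = m),
                     leave_run_out_curve(fits, m))
  })
  trends <- lapply(setNames(measures, measures),
                   function(m) run_trend(fits, m))
  if (!is.null(ema)) {
    items <- setdiff(names(ema), c("participant_id", "run"))
    report <- dplyr::bind_rows(report, reliability_report(ema, items))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(report, file.path(outdir, "report.csv"), na = "")
    readr::write_csv(curves, file.path(outdir, "curves.csv"), na = "")
  }
  list(report = report, curves = curves, trends = trends)
}
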