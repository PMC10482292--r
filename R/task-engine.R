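#' Configure the drifting two-armed bandit task
#'
#' One run of the task presents `n_trials` choices between two options, A and
#' B. Option A's latent win probability follows a bounded Gaussian random
#' walk; option B's probability is its complement, so only A's is stored.
#' Each trial offers integer reward magnitudes that sum to 100 points across
#' the options. A run starts with one "good" option (`init_good`, default
#' 0.8) and one "bad" option (`init_bad`, default 0.2), assigned to A or B
#' with equal probability.
#'
#' @param n_trials Number of trials per run (default 150).
#' @param walk_sd Standard deviation of the Gaussian step applied to the win
#'   probability on every trial.
#' @param walk_bounds Length-2 numeric, the reflecting bounds that keep the
#'   walk inside the open unit interval.
#' @param init_good,init_bad Starting win probabilities of the good and bad
#'   option; they must sum to 1.
#' @param magnitude_low,magnitude_high Integer bounds for option A's reward
#'   magnitude; option B's magnitude is `100 -` A's.
#'
#' @return A `task_config` object (validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
task_config <- function(n_trials = 150,
                        walk_sd = 0.05,
                        walk_bounds = c(0.05, 0.95),
                        init_good = 0.8,
                        init_bad = 0.2,
                        magnitude_low = 1,
                        magnitude_high = 99) {
  cfg <- structure(
    list(n_trials = as.integer(n_trials),
         walk_sd = walk_sd,
         walk_bounds = as.numeric(walk_bounds),
         init_good = init_good,
         init_bad = init_bad,
         magnitude_low = as.integer(magnitude_low),
         magnitude_high = as.integer(magnitude_high)),
    class = "task_config"
  )
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  if (!inherits(cfg, "task_config")) stop("not a task_config", call. = FALSE)
  if (!is_count(cfg$n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cfg$walk_sd) || length(cfg$walk_sd) != 1L ||
      !is.finite(cfg$walk_sd) || cfg$walk_sd < 0) {
    stop("`walk_sd` must be a single non-negative number", call. = FALSE)
  }
  b <- cfg$walk_bounds
  if (length(b) != 2L || !all(is.finite(b)) ||
      !(0 < b[1] && b[1] < b[2] && b[2] < 1)) {
    stop("`walk_bounds` must satisfy 0 < lower < upper < 1", call. = FALSE)
  }
  if (!is_prob(cfg$init_good) || !is_prob(cfg$init_bad) ||
      abs(cfg$init_good + cfg$init_bad - 1) > 1e-12) {
    stop("`init_good` and `init_bad` must be probabilities summing to 1",
         call. = FALSE)
  }
  if (!(cfg$init_good >= b[1] && cfg$init_good <= b[2] &&
        cfg$init_bad >= b[1] && cfg$init_bad <= b[2])) {
    stop("initial probabilities must lie inside `walk_bounds`", call. = FALSE)
  }
  if (!(1 <= cfg$magnitude_low && cfg$magnitude_low <= cfg$magnitude_high &&
        cfg$magnitude_high <= 99)) {
    stop("need 1 <= magnitude_low <= magnitude_high <= 99", call. = FALSE)
  }
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  trials: %d | walk sd: %g in [%g, %g] | start: %g/%g | magnitudes: %d..%d (sum 100)\n",
              x$n_trials, x$walk_sd, x$walk_bounds[1], x$walk_bounds[2],
              x$init_good, x$init_bad, x$magnitude_low, x$magnitude_high))
  invisible(x)
}

# Fold x into [lower, upper] by repeated reflection at the bounds
# (sawtooth map with period 2 * (upper - lower)); vectorized.
reflect_into <- function(x, lower, upper) {
  width <- upper - lower
  y <- (x - lower) %% (2 * width)
  lower + ifelse(y > width, 2 * width - y, y)
}

#' Generate the latent win-probability walk for one run
#'
#' The first value is `init_good` or `init_bad` with probability 0.5 each;
#' each subsequent value adds a Gaussian step of SD `walk_sd` and is
#' reflected back into `walk_bounds`. Option B's probability is defined as
#' `1 - p_win_A` throughout.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n_trials` with option A's win
#'   probability per trial.
#' @export
generate_walk <- function(config = task_config(), seed = NULL) {
  validate_task_config(config)
  with_seed(seed, {
    n <- config$n_trials
    p <- numeric(n)
    p[1] <- if (runif(1) < 0.5) config$init_good else config$init_bad
    if (n > 1L) {
      steps <- rnorm(n - 1L, mean = 0, sd = config$walk_sd)
      for (t in seq_len(n - 1L)) {
        p[t + 1L] <- reflect_into(p[t] + steps[t],
                                  config$walk_bounds[1],
                                  config$walk_bounds[2])
      }
    }
    p
  })
}

#' Generate complementary reward magnitudes for one run
#'
#' Option A's magnitude is drawn uniformly from the integers
#' `magnitude_low:magnitude_high` on every trial; option B's is `100 -` A's,
#' so the two always sum to 100 points.
#'
#' @inheritParams generate_walk
#' @return A tibble with integer columns `f_A` and `f_B`.
#' @export
generate_magnitudes <- function(config = task_config(), seed = NULL) {
  validate_task_config(config)
  with_seed(seed, {
    vals <- seq.int(config$magnitude_low, config$magnitude_high)
    f_A <- vals[sample.int(length(vals), config$n_trials, replace = TRUE)]
    tibble::tibble(f_A = as.integer(f_A), f_B = as.integer(100L - f_A))
  })
}

#' Generate the full stimulus set for one run
#'
#' Combines [generate_walk()] and [generate_magnitudes()] under a single
#' seed into the per-trial stimulus table.
#'
#' @inheritParams generate_walk
#' @return A tibble with columns `trial`, `p_win_A`, `f_A`, `f_B`.
#' @export
#' @examples
#' stim <- generate_run_stimuli(task_config(), seed = 1)
#' all(stim$f_A + stim$f_B == 100)
generate_run_stimuli <- function(config = task_config(), seed = NULL) {
  validate_task_config(config)
  with_seed(seed, {
    p <- generate_walk(config)
    mags <- generate_magnitudes(config)
    tibble::tibble(trial = seq_len(config$n_trials),
                   p_win_A = p,
                   f_A = mags$f_A,
                   f_B = mags$f_B)
  })
}

#' Realize trial outcomes for a sequence of choices
#'
#' On each trial exactly one option is effective: option A with probability
#' `p_win_A[t]`, otherwise B. Choosing the effective option wins that
#' option's magnitude; choosing the other loses the chosen option's
#' magnitude (points are subtracted from the score).
#'
#' @param stimuli Stimulus tibble from [generate_run_stimuli()].
#' @param choices Character vector of `"A"`/`"B"`, one per trial.
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial`, `choice`, `effective_option`,
#'   `r_A` (1 if A was effective), `won`, `points_delta`,
#'   `cumulative_score`.
#' @export
realize_outcomes <- function(stimuli, choices, seed = NULL) {
  assert_columns(stimuli, c("p_win_A", "f_A", "f_B"), "stimuli")
  n <- nrow(stimuli)
  if (length(choices) != n) {
    stop(sprintf("`choices` has length %d but stimuli have %d trials",
                 length(choices), n), call. = FALSE)
  }
  if (!all(choices %in% c("A", "B"))) {
    stop('`choices` must contain only "A" and "B"', call. = FALSE)
  }
  with_seed(seed, {
    effective <- ifelse(runif(n) < stimuli$p_win_A, "A", "B")
    won <- choices == effective
    mag_chosen <- ifelse(choices == "A", stimuli$f_A, stimuli$f_B)
    delta <- as.integer(ifelse(won, mag_chosen, -mag_chosen))
    tibble::tibble(trial = seq_len(n),
                   choice = choices,
                   effective_option = effective,
                   r_A = as.integer(effective == "A"),
                   won = won,
                   points_delta = delta,
                   cumulative_score = cumsum(delta))
  })
}

#' Score a run
#'
#' @param outcomes Outcome tibble from [realize_outcomes()] (or any table
#'   with a `points_delta` column).
#' @return A list with `total_score` and `mean_points_per_trial`, the
#'   model-independent performance measure used throughout.
#' @export
score_run <- function(outcomes) {
  assert_columns(outcomes, "points_delta", "outcomes")
  if (nrow(outcomes) == 0) stop("cannot score an empty run", call. = FALSE)
  total <- sum(outcomes$points_delta)
  list(total_score = total,
       mean_points_per_trial = total / nrow(outcomes))
}
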