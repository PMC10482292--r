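#' Build a parameter grid for the reward landscape
#'
#' Full factorial grid over the four parameters. With the defaults the grid
#' is compact enough for interactive use; dense production grids (tens of
#' thousands of cells, mirroring large player-population simulations) are
#' built by passing finer axes.
#'
#' @param alpha_win,alpha_loss,beta,lam Numeric axes (values within the
#'   parameter bounds).
#' @param reps Simulated runs per cell (>= 1).
#' @return A tibble with one row per cell and a `reps` column.
#' @export
landscape_grid <- function(alpha_win = seq(0.1, 0.9, by = 0.2),
                           alpha_loss = seq(0.1, 0.9, by = 0.2),
                           beta = c(0, 2, 5, 10),
                           lam = c(0, 0.5, 0.9, 1),
                           reps = 10) {
  stopifnot(all(alpha_win >= 0 & alpha_win <= 1),
            all(alpha_loss >= 0 & alpha_loss <= 1),
            all(beta >= 0), all(lam >= 0 & lam <= 1), is_count(reps))
  g <- tidyr::expand_grid(alpha_win = alpha_win, alpha_loss = alpha_loss,
                          beta = beta, lam = lam)
  g$reps <- as.integer(reps)
  g
}

#' Map expected task performance across the parameter space
#'
#' For every grid cell, simulates `reps` full runs (fresh stimuli each) with
#' [simulate_run()] and records the mean and SD of points earned per trial.
#' Agents that weight learned win probabilities heavily (high `lam`), choose
#' decisively (moderate-to-high `beta`), and do not over-react to single
#' losses (moderate `alpha_loss`) earn the most.
#'
#' @param grid Tibble from [landscape_grid()] (columns `alpha_win`,
#'   `alpha_loss`, `beta`, `lam`, and optionally `reps`).
#' @param task_config A [task_config()].
#' @param seed Optional integer seed.
#' @param reps Overrides the grid's `reps` column if given.
#' @return The grid with `mean_reward` and `sd_reward` columns appended
#'   (points per trial).
#' @export
reward_landscape <- function(grid, task_config = banditrl::task_config(),
                             seed = NULL, reps = NULL) {
  assert_columns(grid, c("alpha_win", "alpha_loss", "beta", "lam"), "grid")
  if (!is.null(reps)) grid$reps <- as.integer(reps)
  if (is.null(grid$reps)) grid$reps <- 10L
  stopifnot(all(grid$reps >= 1))
  with_seed(seed, {
    res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      pars <- model_params(grid$alpha_win[i], grid$alpha_loss[i],
                           grid$beta[i], grid$lam[i])
      per_run <- vapply(seq_len(grid$reps[i]), function(r) {
        stim <- generate_run_stimuli(task_config)
        mean(simulate_run(pars, stim)$points_delta)
      }, numeric(1))
      tibble::tibble(mean_reward = mean(per_run),
                     sd_reward = if (length(per_run) > 1) sd(per_run) else NA_real_)
    })
    dplyr::bind_cols(grid, res)
  })
}

#' Binned comparison of performance along a parameter axis
#'
#' Bins a parameter axis at `bin_width` (bin `j` covers
#' `[origin + j * width, origin + (j + 1) * width)`) and compares every pair
#' of occupied bins' mean rewards with Welch's two-sample t-test. No
#' multiplicity correction is applied (raw p-values); empty bins inside the
#' observed span are reported but not compared.
#'
#' @param values Parameter values, one per run.
#' @param rewards Matching mean rewards per run.
#' @param bin_width Bin width (default 0.075).
#' @param origin Left edge of the bin lattice (default 0).
#' @return A list with `bins` (tibble: `bin`, `lower`, `upper`, `n`,
#'   `mean_reward`) and `tests` (tibble of pairwise Welch tests).
#' @export
bin_compare <- function(values, rewards, bin_width = 0.075, origin = 0) {
  if (length(values) != length(rewards)) {
    stop("`values` and `rewards` must have equal length", call. = FALSE)
  }
  ok <- is.finite(values) & is.finite(rewards)
  values <- values[ok]; rewards <- rewards[ok]
  idx <- floor((values - origin) / bin_width + 1e-9)
  span <- seq.int(min(idx), max(idx))
  bins <- purrr::map_dfr(span, function(j) {
    sel <- idx == j
    tibble::tibble(bin = j,
                   lower = origin + j * bin_width,
                   upper = origin + (j + 1) * bin_width,
                   n = sum(sel),
                   mean_reward = if (any(sel)) mean(rewards[sel]) else NA_real_)
  })
  occupied <- bins$bin[bins$n >= 2]
  tests <- NULL
  if (length(occupied) >= 2) {
    pairs <- utils::combn(occupied, 2)
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      xi <- rewards[idx == i]; xj <- rewards[idx == j]
      # essentially-constant data has no testable difference
      tt <- tryCatch(t.test(xi, xj), error = function(e) NULL)
      tibble::tibble(bin_i = i, bin_j = j,
                     mean_diff = mean(xi) - mean(xj),
                     statistic = if (is.null(tt)) NA_real_
                                 else unname(tt$statistic),
                     p_value = if (is.null(tt)) NA_real_ else tt$p.value)
    })
  }
  list(bins = bins, tests = tests)
}
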