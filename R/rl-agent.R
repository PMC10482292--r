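#' The agent's four free parameters
#'
#' Bundles the reinforcement-learning model's parameters: valence-specific
#' learning rates `alpha_win` and `alpha_loss` (delta-rule step sizes applied
#' after won vs lost trials), reward sensitivity `beta` (inverse temperature
#' of the softmax; 0 means fully random choice), and `lam`, the additive
#' weight that trades off the learned win-probability difference against the
#' offered reward-magnitude difference.
#'
#' @param alpha_win,alpha_loss Learning rates in `[0, 1]`.
#' @param beta Reward sensitivity, `>= 0`.
#' @param lam Probability-vs-magnitude weight in `[0, 1]`.
#' @return A `model_params` object.
#' @export
#' @examples
#' model_params(0.7, 0.3, 5, 0.9)
model_params <- function(alpha_win, alpha_loss, beta, lam) {
  p <- structure(list(alpha_win = alpha_win, alpha_loss = alpha_loss,
                      beta = beta, lam = lam),
                 class = "model_params")
  validate_model_params(p)
}

validate_model_params <- function(p) {
  vals <- unlist(p[c("alpha_win", "alpha_loss", "beta", "lam")])
  if (!all(is.finite(vals))) stop("model parameters must be finite", call. = FALSE)
  if (!is_prob(p$alpha_win) || !is_prob(p$alpha_loss) || !is_prob(p$lam)) {
    stop("`alpha_win`, `alpha_loss` and `lam` must lie in [0, 1]", call. = FALSE)
  }
  if (p$beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> alpha_win = %.3f, alpha_loss = %.3f, beta = %.3f, lam = %.3f\n",
              x$alpha_win, x$alpha_loss, x$beta, x$lam))
  invisible(x)
}

#' One delta-rule belief update
#'
#' Moves the belief toward the binary outcome by a fraction `alpha`, where
#' `alpha` is `alpha_win` on trials the chosen option won and `alpha_loss`
#' on trials it lost. The reward prediction error is `r - p_hat`.
#'
#' @param p_hat Current belief (estimated win probability of option A), in
#'   `[0, 1]`.
#' @param r Binary outcome indicator for option A (1 if A was effective).
#' @param chosen_won Logical, whether the chosen option won the trial.
#' @param params A [model_params()].
#' @return Updated belief; stays in `[0, 1]` by construction. Vectorized
#'   over `p_hat`, `r`, `chosen_won`.
#' @export
update_belief <- function(p_hat, r, chosen_won, params) {
  if (any(!is.finite(p_hat)) || any(p_hat < 0 | p_hat > 1)) {
    stop("`p_hat` must lie in [0, 1]", call. = FALSE)
  }
  if (!all(r %in% c(0, 1))) stop("`r` must be binary", call. = FALSE)
  alpha <- ifelse(chosen_won, params$alpha_win, params$alpha_loss)
  p_hat + alpha * (r - p_hat)
}

#' Additive action weight of option A
#'
#' `W(A) = lam * (p_hat_A - (1 - p_hat_A)) + (1 - lam) * (f_A - f_B)`, with
#' magnitudes rescaled to `[0, 1]` (divided by 100) by default so the two
#' differences are commensurate. The weight is antisymmetric:
#' `W(B) = -W(A)`.
#'
#' @param p_hat_A Belief about option A's win probability.
#' @param f_A,f_B Offered reward magnitudes (points).
#' @param lam Probability-vs-magnitude weight in `[0, 1]`.
#' @param rescale_magnitudes Divide magnitudes by 100 before weighting
#'   (default `TRUE`); set `FALSE` for the raw-scale variant.
#' @return Signed weight of option A (vectorized).
#' @export
action_weight <- function(p_hat_A, f_A, f_B, lam, rescale_magnitudes = TRUE) {
  scale <- if (rescale_magnitudes) 1 / 100 else 1
  lam * (2 * p_hat_A - 1) + (1 - lam) * (f_A - f_B) * scale
}

#' Softmax probability of choosing option A
#'
#' `P(A) = exp(beta * W_A) / (exp(beta * W_A) + exp(beta * W_B))`, computed
#' overflow-safely as `plogis(beta * (W_A - W_B))`.
#'
#' @param w_A,w_B Action weights of the two options.
#' @param beta Reward sensitivity (inverse temperature), `>= 0`.
#' @return Probability of choosing A (vectorized).
#' @export
choice_probability <- function(w_A, w_B, beta) {
  plogis(beta * (w_A - w_B))
}

#' Reconstruct the belief trajectory over a run
#'
#' Replays the delta rule over the observed outcome sequence and returns the
#' per-trial beliefs (including the 0.5 prior) and reward prediction errors.
#'
#' @param params A [model_params()].
#' @param data Choice data with columns `choice`, `r_A` (see
#'   [simulate_run()]).
#' @return A list with `p_hat_A` (length `n + 1`) and `rpe` (length `n`).
#' @export
belief_trajectory <- function(params, data) {
  validate_model_params(params)
  assert_columns(data, c("choice", "r_A"), "choice data")
  n <- nrow(data)
  p_hat <- numeric(n + 1L)
  rpe <- numeric(n)
  p_hat[1] <- 0.5
  for (t in seq_len(n)) {
    r <- data$r_A[t]
    rpe[t] <- r - p_hat[t]
    chosen_won <- (data$choice[t] == "A") == (r == 1L)
    p_hat[t + 1L] <- update_belief(p_hat[t], r, chosen_won, params)
  }
  list(p_hat_A = p_hat, rpe = rpe)
}

#' Simulate an agent playing one run
#'
#' Trial loop: compute the action weight from the current belief, sample the
#' choice from the softmax, realize the effective option from the latent win
#' probability, then update the belief with the valence-appropriate learning
#' rate. The belief is initialized at 0.5.
#'
#' @param params A [model_params()].
#' @param stimuli Stimulus tibble from [generate_run_stimuli()].
#' @param seed Optional integer seed.
#' @param rescale_magnitudes Passed to [action_weight()].
#' @return A choice-data tibble with columns `trial`, `choice`, `r_A`,
#'   `f_A`, `f_B`, `won`, `points_delta`, `p_choice_A`.
#' @export
#' @examples
#' stim <- generate_run_stimuli(task_config(), seed = 1)
#' cd <- simulate_run(model_params(0.7, 0.3, 5, 0.9), stim, seed = 2)
#' mean(cd$points_delta)
simulate_run <- function(params, stimuli, seed = NULL,
                         rescale_magnitudes = TRUE) {
  validate_model_params(params)
  assert_columns(stimuli, c("p_win_A", "f_A", "f_B"), "stimuli")
  n <- nrow(stimuli)
  with_seed(seed, {
    u_choice <- runif(n)
    u_outcome <- runif(n)
    choice <- character(n)
    r_A <- integer(n)
    won <- logical(n)
    p_choice_A <- numeric(n)
    p <- 0.5
    for (t in seq_len(n)) {
      w <- action_weight(p, stimuli$f_A[t], stimuli$f_B[t], params$lam,
                         rescale_magnitudes)
      pa <- choice_probability(w, -w, params$beta)
      ch_A <- u_choice[t] < pa
      eff_A <- u_outcome[t] < stimuli$p_win_A[t]
      chosen_won <- ch_A == eff_A
      choice[t] <- if (ch_A) "A" else "B"
      r_A[t] <- as.integer(eff_A)
      won[t] <- chosen_won
      p_choice_A[t] <- pa
      alpha <- if (chosen_won) params$alpha_win else params$alpha_loss
      p <- p + alpha * (r_A[t] - p)
    }
    mag_chosen <- ifelse(choice == "A", stimuli$f_A, stimuli$f_B)
    tibble::tibble(trial = seq_len(n),
                   choice = choice,
                   r_A = r_A,
                   f_A = stimuli$f_A,
                   f_B = stimuli$f_B,
                   won = won,
                   points_delta = as.integer(ifelse(won, mag_chosen, -mag_chosen)),
                   p_choice_A = p_choice_A)
  })
}

#' Log-likelihood of observed choices for one run
#'
#' Reconstructs the belief trajectory from the full outcome sequence exactly
#' as in [simulate_run()] and sums the log softmax probabilities of the
#' observed choices. Per-trial probabilities are floored at `eps` before the
#' log is taken.
#'
#' @param params A [model_params()].
#' @param data Choice data with columns `choice`, `r_A`, `f_A`, `f_B`.
#' @param rescale_magnitudes Passed to [action_weight()].
#' @param eps Floor for per-trial choice probabilities (default `1e-12`).
#' @return The run log-likelihood (a single non-positive number).
#' @export
run_log_likelihood <- function(params, data, rescale_magnitudes = TRUE,
                               eps = 1e-12) {
  validate_model_params(params)
  assert_columns(data, c("choice", "r_A", "f_A", "f_B"), "choice data")
  if (!all(data$r_A %in% c(0L, 1L))) stop("`r_A` must be binary", call. = FALSE)
  lens <- c(length(data$choice), length(data$r_A),
            length(data$f_A), length(data$f_B))
  if (length(unique(lens)) != 1L) {
    stop("choice-data columns have mismatched lengths", call. = FALSE)
  }
  cpp_run_loglik(as.integer(data$choice == "A"), as.integer(data$r_A),
                 as.numeric(data$f_A), as.numeric(data$f_B),
                 params$alpha_win, params$alpha_loss, params$beta,
                 params$lam,
                 if (rescale_magnitudes) 1 / 100 else 1,
                 eps)
}
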