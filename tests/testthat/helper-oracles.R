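# Independent reference implementations used as oracles. These deliberately
# follow a different computational route than the package (explicit
# exponential ratios, both options' beliefs tracked separately, textbook
# ANOVA formulas) so agreement is evidence, not tautology.

# Per-trial, unvectorized run log-likelihood; tracks p(A) and p(B) separately
# and evaluates the softmax as an explicit ratio of exponentials.
oracle_loglik <- function(alpha_win, alpha_loss, beta, lam,
                          choice, r_A, f_A, f_B,
                          rescale = TRUE, eps = 1e-12) {
  pA <- 0.5
  ll <- 0
  for (t in seq_along(choice)) {
    pB <- 1 - pA
    fa <- if (rescale) f_A[t] / 100 else f_A[t]
    fb <- if (rescale) f_B[t] / 100 else f_B[t]
    wA <- lam * (pA - pB) + (1 - lam) * (fa - fb)
    wB <- lam * (pB - pA) + (1 - lam) * (fb - fa)
    den <- exp(wA * beta) + exp(wB * beta)
    pr <- if (choice[t] == "A") exp(wA * beta) / den else exp(wB * beta) / den
    ll <- ll + log(max(pr, eps))
    won <- (choice[t] == "A") == (r_A[t] == 1)
    a <- if (won) alpha_win else alpha_loss
    pA <- pA + a * (r_A[t] - pA)
  }
  ll
}

# Closed-form one-way random-effects ANOVA ICC for a balanced table.
oracle_anova_icc <- function(values, groups) {
  k <- length(unique(groups))
  n <- length(values) / k
  grand <- mean(values)
  m <- tapply(values, groups, mean)
  msb <- n * sum((m - grand)^2) / (k - 1)
  msw <- sum((values - m[groups])^2) / (length(values) - k)
  vb <- (msb - msw) / n
  vb / (vb + msw)
}

# Random choice data for oracle-equivalence checks: simulated gameplay under
# random parameters so the belief trajectory is exercised realistically.
random_choice_data <- function(n_trials = 150, seed = NULL,
                               cfg = task_config(n_trials = n_trials)) {
  gen <- model_params(runif(1), runif(1), runif(1, 0, 10), runif(1))
  stim <- generate_run_stimuli(cfg, seed = seed)
  simulate_run(gen, stim, seed = if (is.null(seed)) NULL else seed + 1L)
}

# Best log-likelihood on a coarse grid over the parameter box (optimizer
# oracle: any MLE must do at least this well).
grid_search_loglik <- function(data, n_axis = 9, beta_max = 20) {
  ax01 <- seq(0, 1, length.out = n_axis)
  axb <- seq(0, beta_max, length.out = n_axis)
  best <- -Inf
  for (aw in ax01) for (al in ax01) for (b in axb) for (lm in ax01) {
    ll <- run_log_likelihood(model_params(aw, al, b, lm), data)
    if (ll > best) best <- ll
  }
  best
}
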