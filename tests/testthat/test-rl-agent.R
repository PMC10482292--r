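test_that("model parameters validate their bounds", {
  expect_s3_class(model_params(0.5, 0.5, 2, 0.9), "model_params")
  expect_error(model_params(-0.1, 0.5, 2, 0.9), "\\[0, 1\\]")
  expect_error(model_params(0.5, 1.2, 2, 0.9), "\\[0, 1\\]")
  expect_error(model_params(0.5, 0.5, -1, 0.9), "beta")
  expect_error(model_params(0.5, 0.5, Inf, 0.9), "finite")
})

test_that("the delta rule updates beliefs with valence-specific rates", {
  pars <- model_params(0.5, 0.1, 2, 0.9)
  expect_equal(update_belief(0.5, 1, TRUE, pars), 0.75)
  # zero learning rate leaves any belief unchanged
  frozen <- model_params(0, 0, 2, 0.9)
  expect_equal(update_belief(c(0.2, 0.9), c(1, 0), c(TRUE, FALSE), frozen),
               c(0.2, 0.9))
  # zero prediction error
  expect_equal(update_belief(1, 1, TRUE, pars), 1)
  # loss trials use alpha_loss
  expect_equal(update_belief(0.5, 1, FALSE, pars), 0.5 + 0.1 * 0.5)
  expect_error(update_belief(1.2, 1, TRUE, pars), "\\[0, 1\\]")
})

test_that("action weights mix probability and magnitude and are antisymmetric", {
  expect_equal(action_weight(0.5, 50, 50, lam = 1), 0)
  expect_equal(action_weight(0.3, 71, 29, lam = 0), 0.42)
  expect_equal(action_weight(0.3, 71, 29, lam = 0, rescale_magnitudes = FALSE),
               42)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(1); fa <- sample(1:99, 1); lm <- runif(1)
    wA <- action_weight(p, fa, 100 - fa, lm)
    wB <- action_weight(1 - p, 100 - fa, fa, lm)
    expect_equal(wB, -wA)
  }
})

test_that("softmax choice probabilities are symmetric, normalized, and match the logistic closed form", {
  expect_equal(choice_probability(3, -1, beta = 0), 0.5)
  expect_equal(choice_probability(0.4, 0.4, beta = 7), 0.5)
  expect_equal(choice_probability(1, -1, beta = 5), 1 / (1 + exp(-10)),
               tolerance = 1e-12)
  set.seed(3)
  wa <- rnorm(20); wb <- rnorm(20); b <- runif(20, 0, 10)
  expect_equal(choice_probability(wa, wb, b) + choice_probability(wb, wa, b),
               rep(1, 20))
})

test_that("simulation is deterministic under a seed and obeys the exploitative limit", {
  stim <- generate_run_stimuli(task_config(), seed = 5)
  pars <- model_params(0.7, 0.3, 5, 0.9)
  expect_identical(simulate_run(pars, stim, seed = 6),
                   simulate_run(pars, stim, seed = 6))
  # pinned belief + huge beta: after the first feedback the agent always
  # chooses the certain option
  pinned <- tibble::tibble(trial = 1:50, p_win_A = rep(1 - 1e-12, 50),
                           f_A = rep(50L, 50), f_B = rep(50L, 50))
  cd <- simulate_run(model_params(1, 1, 50, 1), pinned, seed = 7)
  expect_true(all(cd$choice[-1] == "A"))
  expect_true(all(cd$won[-1]))
})

test_that("a learning agent outperforms a random agent on the same task", {
  cfg <- task_config()
  pars <- model_params(0.7, 0.3, 5, 1)
  set.seed(8)
  agent <- vapply(1:60, function(i) {
    mean(simulate_run(pars, generate_run_stimuli(cfg))$points_delta)
  }, numeric(1))
  rand <- vapply(1:60, function(i) {
    stim <- generate_run_stimuli(cfg)
    choices <- sample(c("A", "B"), cfg$n_trials, replace = TRUE)
    score_run(realize_outcomes(stim, choices))$mean_points_per_trial
  }, numeric(1))
  expect_gt(mean(agent), mean(rand) + 5)
})

test_that("beliefs stay in [0, 1] and prediction errors follow the definition", {
  set.seed(9)
  for (i in 1:20) {
    pars <- model_params(runif(1), runif(1), runif(1, 0, 10), runif(1))
    cd <- random_choice_data(80)
    tr <- belief_trajectory(pars, cd)
    expect_true(all(tr$p_hat_A >= 0 & tr$p_hat_A <= 1))
    expect_equal(tr$rpe, cd$r_A - tr$p_hat_A[seq_len(nrow(cd))])
  }
})

test_that("the flat-softmax likelihood hits its closed form and certain choices cost nothing", {
  cd <- random_choice_data(150, seed = 10)
  flat <- model_params(0.7, 0.3, 0, 0.9)
  expect_equal(run_log_likelihood(flat, cd), 150 * log(0.5),
               tolerance = 1e-12)
  # one trial whose choice probability is forced to ~1
  one <- tibble::tibble(choice = "A", r_A = 1L, f_A = 99, f_B = 1)
  expect_equal(run_log_likelihood(model_params(0.5, 0.5, 1e6, 0), one), 0,
               tolerance = 1e-9)
})

test_that("the likelihood matches the per-trial oracle and is invariant to relabeling the options", {
  set.seed(12)
  for (i in 1:10) {
    cd <- random_choice_data(100)
    pars <- model_params(runif(1), runif(1), runif(1, 0, 10), runif(1))
    expect_equal(run_log_likelihood(pars, cd),
                 oracle_loglik(pars$alpha_win, pars$alpha_loss, pars$beta,
                               pars$lam, cd$choice, cd$r_A, cd$f_A, cd$f_B),
                 tolerance = 1e-10)
    relabeled <- tibble::tibble(
      choice = ifelse(cd$choice == "A", "B", "A"),
      r_A = 1L - cd$r_A, f_A = cd$f_B, f_B = cd$f_A)
    expect_equal(run_log_likelihood(pars, relabeled),
                 run_log_likelihood(pars, cd), tolerance = 1e-10)
  }
})

test_that("the generating parameters dominate perturbed ones in expected likelihood", {
  cfg <- task_config()
  gen <- model_params(0.7, 0.25, 5, 0.95)
  perturbed <- list(model_params(0.2, 0.8, 5, 0.95),
                    model_params(0.7, 0.25, 0.5, 0.95),
                    model_params(0.7, 0.25, 5, 0.3))
  set.seed(13)
  runs <- lapply(1:40, function(i) {
    simulate_run(gen, generate_run_stimuli(cfg))
  })
  ll_gen <- mean(vapply(runs, function(cd) run_log_likelihood(gen, cd),
                        numeric(1)))
  for (bad in perturbed) {
    ll_bad <- mean(vapply(runs, function(cd) run_log_likelihood(bad, cd),
                          numeric(1)))
    expect_gt(ll_gen, ll_bad)
  }
})
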