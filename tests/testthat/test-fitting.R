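test_that("the MLE dominates the generating parameters and stays inside the box", {
  cfg <- task_config()
  set.seed(21)
  for (i in 1:10) {
    gen <- model_params(runif(1), runif(1), runif(1, 1, 8), runif(1))
    cd <- simulate_run(gen, generate_run_stimuli(cfg))
    fit <- fit_run(cd, seed = 100 + i)
    expect_gte(fit$log_likelihood, run_log_likelihood(gen, cd) - 1e-8)
    expect_lte(fit$log_likelihood, 0)
    p <- fit$params
    expect_true(p$alpha_win >= 0 && p$alpha_win <= 1)
    expect_true(p$alpha_loss >= 0 && p$alpha_loss <= 1)
    expect_true(p$beta >= 0 && p$beta <= 20)
    expect_true(p$lam >= 0 && p$lam <= 1)
  }
})

test_that("fitting is deterministic under a seed and flags boundary estimates", {
  cd <- simulate_run(model_params(0.9, 0.1, 8, 1),
                     generate_run_stimuli(task_config(), seed = 22), seed = 23)
  f1 <- fit_run(cd, seed = 24)
  f2 <- fit_run(cd, seed = 24)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_named(f1$at_bound, c("alpha_win", "alpha_loss", "beta", "lam"))
  expect_true(f1$converged)
  expect_error(fit_run(cd[1, ]), "2 trials")
})

test_that("the optimizer beats a coarse grid search", {
  set.seed(25)
  for (i in 1:5) {
    cd <- random_choice_data(150)
    fit <- fit_run(cd, seed = 200 + i)
    expect_gte(fit$log_likelihood, grid_search_loglik(cd, n_axis = 5) - 1e-6)
  }
})

test_that("a beta box pinned at zero collapses every random-choice fit to the flat-model likelihood", {
  cfg0 <- fit_config(n_starts = 2, beta_max = 1e-9)
  thr <- derive_random_choice_threshold(task_config(), cfg0, n_sims = 100,
                                        seed = 26)
  lls <- attr(thr, "log_likelihoods")
  expect_equal(lls, rep(150 * log(0.5), 100), tolerance = 1e-6)
  expect_equal(as.numeric(thr), 150 * log(0.5), tolerance = 1e-6)
})

test_that("the random-choice threshold is stable across seeds and above the flat model", {
  t1 <- derive_random_choice_threshold(n_sims = 1000, seed = 27)
  t2 <- derive_random_choice_threshold(n_sims = 1000, seed = 28)
  expect_gte(as.numeric(t1), 150 * log(0.5))
  expect_gte(as.numeric(t2), 150 * log(0.5))
  expect_lt(abs(as.numeric(t1) - as.numeric(t2)), 0.5)
  # ~95% of fresh random-choice runs fall below the derived cutoff
  expect_lt(abs(mean(attr(t2, "log_likelihoods") < as.numeric(t1)) - 0.95),
            0.03)
  expect_error(derive_random_choice_threshold(n_sims = 50), "at least 100")
})

test_that("quality control excludes strictly-below-threshold runs and sparse participants", {
  fits <- tibble::tibble(
    participant_id = c(rep("p1", 10), rep("p2", 10), rep("p3", 3)),
    run = c(1:10, 1:10, 1:3),
    log_likelihood = c(rep(-50, 10),                 # p1: all clean
                       -100.13, rep(-50, 8), -150,   # p2: one at, one below
                       rep(-50, 3)))                 # p3: too few runs
  qc <- qc_filter(fits, threshold = -100.13, min_runs = 9)
  # exactly at the threshold is kept (strict "<")
  expect_true(any(qc$kept$participant_id == "p2" & qc$kept$run == 1))
  expect_true(any(qc$excluded_runs$participant_id == "p2" &
                    qc$excluded_runs$run == 10))
  expect_identical(qc$excluded_participants, "p3")
  expect_equal(nrow(qc$kept), 19)
  expect_equal(qc$exclusion_fraction, 4 / 23)
  # a clean cohort loses nothing
  clean <- qc_filter(fits[1:20, ], threshold = -200, min_runs = 10)
  expect_equal(clean$exclusion_fraction, 0)
})

test_that("the response-time filter keeps the plausible interior", {
  trials <- tibble::tibble(rt_ms = c(20, 800, 12000, 50, 10000, 51, 9999, NA))
  kept <- rt_filter(trials)
  expect_equal(kept$rt_ms, c(800, 51, 9999))
  expect_equal(attr(kept, "fraction_removed"), 5 / 8)
  expect_error(rt_filter(tibble::tibble(x = 1)), "rt_ms")
})

test_that("population parameter draws respect bounds and moments", {
  ps <- sample_param_sets(400, seed = 29)
  expect_true(all(ps$alpha_win >= 0 & ps$alpha_win <= 1))
  expect_true(all(ps$alpha_loss >= 0 & ps$alpha_loss <= 1))
  expect_true(all(ps$lam >= 0 & ps$lam <= 1))
  expect_true(all(ps$beta >= 0 & ps$beta <= 20))
  expect_lt(abs(mean(ps$beta) - 4.98), 0.4)
})

test_that("recovery is near-perfect in the high-identifiability limit", {
  # near-deterministic probability-only agents: lam should come back ~1
  sets <- tibble::tibble(alpha_win = runif(50, 0.4, 0.8),
                         alpha_loss = runif(50, 0.1, 0.5),
                         beta = runif(50, 12, 18),
                         lam = rep(1, 50))
  rec <- parameter_recovery(sets, seed = 30)
  expect_gt(mean(rec$fits$lam_hat), 0.9)
  expect_gt(median(rec$fits$lam_hat), 0.97)
  expect_error(parameter_recovery(sets[1:10, ]), "at least 50")
})

test_that("recovery improves with run length", {
  ps <- sample_param_sets(60, seed = 31)
  mean_r <- vapply(c(75, 300), function(nt) {
    rec <- parameter_recovery(ps, task_config(n_trials = nt), seed = 32)
    mean(rec$correlations$pearson)
  }, numeric(1))
  expect_gt(mean_r[2], mean_r[1])
})
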