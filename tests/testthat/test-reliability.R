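toy_icc_table <- function() {
  # balanced 3 x 3 fixture; closed-form one-way ANOVA gives ICC = 7/13
  tibble::tibble(participant_id = rep(c("a", "b", "c"), each = 3),
                 run = rep(1:3, 3),
                 y = c(1, 2, 3, 2, 4, 6, 5, 5, 8))
}

test_that("ICC is 1 with zero within-variance and ~0 without clustering", {
  const <- tibble::tibble(participant_id = rep(c("a", "b", "c"), each = 4),
                          run = rep(1:4, 3),
                          y = rep(c(1, 5, 9), each = 4))
  expect_equal(icc_absolute(const, "y")$icc, 1, tolerance = 1e-8)
  expect_equal(icc_absolute(const, "y", method = "anova")$icc, 1,
               tolerance = 1e-8)

  set.seed(41)
  iid <- tibble::tibble(participant_id = rep(sprintf("p%02d", 1:60), each = 10),
                        run = rep(1:10, 60),
                        y = rnorm(600))
  expect_lt(icc_absolute(iid, "y", method = "anova")$icc, 0.06)
  expect_lt(icc_absolute(iid, "y")$icc, 0.06)

  allsame <- tibble::tibble(participant_id = rep(c("a", "b"), each = 3),
                            run = rep(1:3, 2), y = rep(1, 6))
  expect_error(icc_absolute(allsame, "y"), "constant")
  expect_error(icc_absolute(const[1:4, ], "y"), "2 participants")
  dup <- const; dup$run <- 1
  expect_error(icc_absolute(dup, "y"), "unique")
})

test_that("both ICC estimators match the closed-form ANOVA oracle on a balanced table", {
  tab <- toy_icc_table()
  oracle <- oracle_anova_icc(tab$y, tab$participant_id)
  expect_equal(oracle, 7 / 13, tolerance = 1e-12)
  expect_equal(icc_absolute(tab, "y", method = "anova")$icc, oracle,
               tolerance = 1e-6)
  expect_equal(icc_absolute(tab, "y", method = "reml")$icc, oracle,
               tolerance = 1e-4)
  res <- icc_absolute(tab, "y")
  expect_equal(res$icc, res$var_between / (res$var_between + res$var_within))
  expect_gte(res$var_between, 0)
  expect_gte(res$var_within, 0)
})

test_that("ICC is invariant to participant-constant offsets; conditional ICC also to shared run effects", {
  set.seed(42)
  n <- 150; k <- 10
  base <- tibble::tibble(
    participant_id = rep(sprintf("p%03d", 1:n), each = k),
    run = rep(1:k, n),
    y = rep(rnorm(n, 0, 1), each = k) + rnorm(n * k, 0, 1))  # designed ICC 0.5
  shifted <- base
  shifted$y <- base$y + rep(rnorm(n, 10, 3), each = k)
  expect_equal(icc_absolute(shifted, "y")$icc,
               # participant-constant offsets only move the between component
               (icc_absolute(base, "y")$var_between + 9) /
                 (icc_absolute(base, "y")$var_between + 9 +
                    icc_absolute(base, "y")$var_within),
               tolerance = 0.05)

  trended <- base
  trended$y <- base$y + 4 * log(trended$run)   # strong shared practice effect
  unc <- icc_absolute(trended, "y")$icc
  cond <- icc_conditional(trended, "y")$icc
  expect_lt(unc, 0.35)                          # trend inflates within-variance
  expect_lt(abs(cond - 0.5), 0.07)              # conditional recovers design
  expect_lt(abs(icc_conditional(trended, "y", method = "anova")$icc - cond),
            0.02)
  # without a trend the two ICCs agree
  expect_lt(abs(icc_conditional(base, "y")$icc - icc_absolute(base, "y")$icc),
            0.02)
})

test_that("correlation magnitudes classify per the standard cutoffs", {
  expect_equal(classify_correlation(c(0.30, 0.50, 0.70)),
               c("low", "modest", "high"))
  expect_equal(classify_correlation(c(0.35, 0.355, 0.36, 0.67, 0.671)),
               c("low", "low", "modest", "modest", "high"))
  expect_equal(classify_correlation(c(-0.9, -0.5, 0)),
               c("high", "modest", "low"))
  expect_equal(classify_correlation(NA), NA_character_)
  expect_error(classify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("the leave-run-out curve matches a hand-computed toy and rank invariances", {
  tab <- toy_icc_table()
  tab$y[9] <- 1   # participant c drops on run 3: (5, 5, 1)
  curve <- leave_run_out_curve(tab, "y")
  expect_equal(curve$spearman_r, c(0.5, 0.5, -0.5))
  expect_equal(curve$n, c(3, 3, 3))
  expect_equal(curve$taylor_class, c("modest", "modest", "modest"))

  # perfect rank consistency gives a constant curve of 1
  set.seed(43)
  traits <- rnorm(12)
  consist <- tibble::tibble(participant_id = rep(sprintf("p%02d", 1:12), each = 5),
                            run = rep(1:5, 12),
                            y = rep(traits, each = 5) + rep(1:5 / 10, 12))
  expect_equal(leave_run_out_curve(consist, "y")$spearman_r, rep(1, 5))

  # rank-based in the held-out value: exactly invariant to linear rescaling,
  # and stable (not exactly invariant) under nonlinear monotone transforms,
  # which commute with ranks but not with the held-out raw-scale mean
  set.seed(44)
  noisy <- tibble::tibble(participant_id = rep(sprintf("p%02d", 1:20), each = 6),
                          run = rep(1:6, 20),
                          y = rep(rnorm(20), each = 6) + rnorm(120, 0, 0.5))
  lin <- noisy; lin$y <- 3 * noisy$y - 7
  expect_equal(leave_run_out_curve(noisy, "y")$spearman_r,
               leave_run_out_curve(lin, "y")$spearman_r)
  trans <- noisy; trans$y <- exp(noisy$y)
  expect_lt(max(abs(leave_run_out_curve(noisy, "y")$spearman_r -
                      leave_run_out_curve(trans, "y")$spearman_r)), 0.05)
  expect_error(leave_run_out_curve(noisy[noisy$run < 3, ], "y"), "3 distinct")
})

test_that("runs observed in too few participants are reported as missing", {
  tab <- toy_icc_table()
  extra <- tibble::tibble(participant_id = "a", run = 4, y = 2)
  curve <- leave_run_out_curve(dplyr::bind_rows(tab, extra), "y")
  expect_true(is.na(curve$spearman_r[curve$run == 4]))
  expect_true(is.na(curve$taylor_class[curve$run == 4]))
})

test_that("the practice-trend model recovers an injected log-run slope and nulls", {
  set.seed(45)
  n <- 200; k <- 12
  tab <- tibble::tibble(
    participant_id = rep(sprintf("p%03d", 1:n), each = k),
    run = rep(1:k, n),
    y = rep(rnorm(n, 0.4, 0.15), each = k) - 0.06 * log(rep(1:k, n)) +
      rnorm(n * k, 0, 0.1))
  tr <- run_trend(tab, "y")
  expect_lt(abs(tr$slope - (-0.06)), 0.02)
  expect_lt(tr$p_value, 0.001)

  # constant measure: exactly zero slope, no test
  const <- tab; const$y <- 1
  tr0 <- run_trend(const, "y")
  expect_identical(tr0$slope, 0)

  # type-I calibration on small null cohorts
  cover <- vapply(1:40, function(i) {
    null <- tibble::tibble(
      participant_id = rep(sprintf("q%02d", 1:30), each = 8),
      run = rep(1:8, 30),
      y = rep(rnorm(30), each = 8) + rnorm(240, 0, 0.5))
    tr <- run_trend(null, "y")
    abs(tr$slope) < 1.96 * tr$se
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("performance correlations produce a proper matrix", {
  set.seed(46)
  tab <- tibble::tibble(beta = runif(50, 0, 10))
  tab$mean_reward <- 2 * tab$beta + rnorm(50)
  m <- performance_correlations(tab, c("beta", "mean_reward"))
  expect_equal(diag(m), c(beta = 1, mean_reward = 1))
  expect_equal(m[1, 2], m[2, 1])
  expect_gt(m["beta", "mean_reward"], 0.9)
})

test_that("the reliability report carries descriptives and both ICC columns", {
  set.seed(47)
  n <- 40; k <- 6
  tab <- tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:n), each = k),
    run = rep(1:k, n),
    m1 = rep(rnorm(n, 50, 5), each = k) + rnorm(n * k, 0, 5))
  rep_tab <- reliability_report(tab, "m1")
  expect_named(rep_tab, c("measure", "mean", "sd", "median", "p10", "p90",
                          "icc_unc", "icc_cond"))
  expect_equal(rep_tab$median, median(tab$m1))
  expect_true(rep_tab$icc_unc >= 0 && rep_tab$icc_unc <= 1)
})
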