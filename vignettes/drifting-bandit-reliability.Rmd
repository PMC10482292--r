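---
title: "Methods: reward learning, model fitting, and test-retest reliability in a drifting two-armed bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reward learning, model fitting, and test-retest reliability in a drifting two-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the task and agent
model, the estimation and quality-control machinery, the psychometric
stage, and — importantly — the decisions taken where the design was
genuinely open, with the reasoning behind each.

## The task

One *run* is 150 trials of a two-option probabilistic reward-learning task.
Option A's latent win probability follows a Gaussian random walk reflected
into `(0.05, 0.95)`; option B's probability is its complement, so exactly
one option is effective per trial. Each run starts with a "good" (0.8) and
a "bad" (0.2) option, assigned to A/B with equal probability, which forces
continual relearning across runs and defeats meta-learning of reversal
times. Reward magnitudes are drawn fresh every trial as uniform integers
with `f_A + f_B = 100` points; choosing the effective option wins the
chosen magnitude, otherwise the chosen magnitude is subtracted from the
score. The model-independent performance measure is the mean points earned
per trial.

Two walk settings are not dictated by the task description and are package
choices: the per-trial step SD (`walk_sd = 0.05`) and the reflecting bounds
(`0.05`–`0.95`). The step SD keeps the good and bad options distinguishable
over a 150-trial run while producing visible contingency drift; materially
smaller values make the run a near-static bandit, materially larger ones
make the walk forget its good/bad start within a few dozen trials. Both are
configurable in `task_config()`. The walk operates on the probability scale
(not log-odds) with reflection at the bounds — the simplest reading of a
"Gaussian random walk" on probabilities; reflection (rather than clamping)
avoids probability mass accumulating at the bounds.

One distributional consequence worth knowing: the two-point 0.8/0.2 start
has cross-run variance 0.09, *larger* than the walk's stationary variance
inside the bounds (~0.0675), so the marginal variance across runs shrinks
slightly over trials even as the distribution spreads from two spikes into
the whole interior. The test suite therefore checks interior spread
conditional on the start, not raw variance growth.

## The agent

Four parameters: learning rates `alpha_win, alpha_loss` in `[0, 1]`, reward
sensitivity `beta >= 0` (unitless inverse temperature), and the
probability-versus-magnitude weight `lambda` in `[0, 1]`.

Beliefs follow a delta rule on a single quantity, the estimated win
probability of option A: `p <- p + alpha * (r - p)` with `r` the binary
indicator that A was effective. Tracking one belief and deriving B's as
`1 - p` is forced by the task structure: feedback reveals the effective
option on every trial and the true probabilities are complementary.

The action weight is additive,
`W(A) = lambda * (2p - 1) + (1 - lambda) * (f_A - f_B) / 100`, and choice
is softmax, `P(A) = logistic(beta * (W(A) - W(B)))` with `W(B) = -W(A)`.

Three open points were settled as follows:

- **Valence keying.** "Separate learning rates for wins and losses" is
  keyed to the *chosen option's outcome* (chosen option won → `alpha_win`).
  Keying to the sign of the chosen option's prediction error is
  algebraically identical here (with binary outcomes the chosen option's
  RPE is positive exactly when it won), so the only genuinely different
  reading — keying to option A's outcome regardless of choice — was
  rejected as behaviorally meaningless.
- **Magnitude rescaling.** Magnitudes enter the weight divided by 100, so
  the probability difference (range ±1) and the magnitude difference
  (range ±0.98) are commensurate and `lambda = 0.5` is the point of equal
  weighting — consistent with describing `lambda < .5` as magnitude-driven
  choice. Without rescaling, the crossover would sit near `lambda = 0.97`
  and reported `beta` values in the 2–9 range would imply absurdly
  deterministic choices. The raw-scale variant remains available
  (`rescale_magnitudes = FALSE`).
- **Prior belief.** `p = 0.5` at run start: symmetric ignorance; the agent
  cannot know which option starts good.

## Estimation and quality control

`fit_run()` maximizes the run log-likelihood (beliefs reconstructed from
the full outcome sequence, exactly as in forward simulation) over the
parameter box by L-BFGS-B from 10 starting points drawn uniformly in the
box. Multi-start matters: the likelihood is multi-modal in the two learning
rates. `beta`'s conceptually unbounded range is boxed at `beta_max = 20`;
the reference population's 90th percentile is 9.4, so the bound is
non-binding for realistic behavior, and boundary hits are flagged
(`at_bound`). Per-trial choice probabilities are floored at `1e-12` before
logging — numerical safety with no material bias (the floor binds only when
a near-deterministic model is contradicted by an observed choice). The
likelihood inner loop is compiled (Rcpp), evaluates the chosen option's
probability directly on the logit scale to avoid cancellation near
certainty, and is verified in the test suite against an independent
per-trial R implementation to 1e-10 and against a coarse grid-search oracle.

Quality control reproduces the simulation-derived random-choice criterion:
simulate runs of uniformly random choices on fresh stimuli, fit each with
the full model, and take the 95th percentile of the fitted log-likelihoods
(≈ −100.1 for 150-trial runs; the flat-choice baseline is
`150 ln 0.5 ≈ −103.97`, and fitting four free parameters to noise buys back
a few points). Runs *strictly below* the threshold are excluded; runs
exactly at it are kept. Participants with fewer than 10 surviving runs are
then dropped. The default 1,000 threshold simulations give a Monte-Carlo SE
near 0.15 on the threshold; use 10,000 for production estimates. The
response-time filter keeps trials with `50 < rt < 10000` ms — the interval
endpoints are read as the *plausible interior*, since excluding the
interior would remove essentially all trials rather than the ~1% an
extreme-RT filter is meant to catch.

`parameter_recovery()` simulates one run per generating parameter set and
refits it. Recovery quality is a property of the generating distribution
as much as of the estimator: with draws from the reference population
moments (truncated normals; `sample_param_sets()`), the loss learning rate
recovers best (Pearson r ≈ .9) while `alpha_win`, `beta`, and `lambda`
recover in the .5–.65 range from a single 150-trial run — high learning
rates after wins produce near-identical choice streams, and with `lambda`
near 1 the magnitude weight is informed by little data. The test suite
asserts the structural facts (recovery improves with run length; `lambda`
returns ≈ 1 in the high-identifiability limit; `alpha_loss` is the
best-recovered parameter) rather than a universal floor.

## Longitudinal psychometrics

The unit of repeated measurement is the run. For any run-level measure:

- **ICC** (`icc_absolute()`): one-way random-effects, absolute agreement —
  between-participant variance over total. Estimated by REML
  (`lme4::lmer(y ~ 1 + (1 | participant))`) or by method-of-moments ANOVA
  (`method = "anova"`, negative between-variance truncated at 0); the two
  agree on balanced tables, and the REML route handles the unbalanced
  10–31-runs-per-participant tables gracefully.
- **Conditional ICC** (`icc_conditional()`): identical decomposition after
  removing a fixed effect of `log(run)` shared by all participants, so a
  group-level practice trend no longer counts as within-participant
  instability. The trend is modeled as a `log(run)` covariate (not run as a
  fixed factor), matching the practice-effect model used for trends; with a
  strong shared trend the unconditional ICC drops while the conditional one
  recovers the designed variance ratio.
- **Leave-run-out curve** (`leave_run_out_curve()`): for each run, the
  Spearman correlation (average ranks on ties) across participants between
  that run's value and the mean of the participant's other runs; runs with
  fewer than 3 complete pairs are reported as missing. Correlation
  magnitudes are labeled low (< .35), modest (.36–.67), high (> .67); the
  undefined gap `[.35, .36)` maps to low.
- **Practice trends** (`run_trend()`): `y ~ log(run)` with random intercept
  and random `log(run)` slope per participant; on non-convergence or
  singular fits it falls back to random intercepts only and says so. The
  default p-value uses a normal approximation of the t statistic —
  indistinguishable from small-sample corrections at hundreds of
  participants — with a Satterthwaite option (lmerTest) for small cohorts.

## The reward landscape

`reward_landscape()` maps expected points per trial over the parameter
grid by forward simulation (fresh stimuli per repetition), reproducing the
qualitative structure of large player-population simulations: reward is
insensitive to `alpha_win`, peaks at moderate `alpha_loss` (not abandoning
a preferred option after a single loss tracks the latent walk better),
rises with `beta` to a plateau above ≈ 5, and is maximal at `lambda = 1`.
`bin_compare()` runs the associated binned contrasts (default width .075)
with pairwise Welch tests and no multiplicity correction (raw p-values, as
is conventional for these descriptive contrasts; correct downstream if
needed). The default test grid is deliberately small; production-scale
grids (tens of thousands of cells) are just larger axes.

## The synthetic cohort generator

`generate_cohort()` produces a full synthetic study from a
`cohort_design()`: per-participant base parameters (truncated-normal,
between-SD), per-run true parameters (base + iid truncated-Gaussian
within-SD jitter + optional `slope * log(run)` + optional early-run noise
inflation decaying exponentially), simulated gameplay, lognormal response
times with a participant location shift and a `log(run)` speed-up, and
0–100 state items from an additive between/within model. The default
design (`design_from_table1()`) matches the reference sample's reported
means and SDs, with the between/within split reverse-engineered from the
reported ICCs (`sd_between = sd * sqrt(ICC)`) because within-participant
SDs were not reported separately.

What the generator deliberately does *not* emulate: state items are
independent of gameplay (state–behavior coupling is a research question,
not a fixture); run counts are uniform over the configured range rather
than matching the empirical attrition curve; parameter jitter is iid
Gaussian across runs (no autocorrelation); and truncation into `[0, 1]`
slightly attenuates designed trends and variances near the bounds (visible
as recovered trend slopes a few thousandths shallower than designed).
Passing recovery tests on these cohorts therefore demonstrates estimator
correctness under the designed variance structure — not that real
behavioral data meet those assumptions.

## Problem sizes and numerical choices in the test suite

The suite checks designed-ICC recovery at 400 participants × 30 runs
(±0.05), trend recovery at 200 participants (±0.02 around a −0.06
log-run slope), the QC threshold at 1,000 simulations, recovery at 500
parameter sets, and landscape contrasts at 200–250 repetitions per cell —
sizes chosen so Monte-Carlo error is a small fraction of each tolerance
while the whole suite runs in minutes. Stochastic assertions use margins of
at least four standard errors derived from the known per-run variance.

## Known limitations

- Per-run maximum likelihood treats runs as independent; no hierarchical
  pooling across a participant's runs, and near-deterministic runs can
  return boundary estimates (flagged, not shrunk).
- The conditional ICC removes only a *shared* log-run trend; idiosyncratic
  practice trajectories remain within-participant variance.
- Recovery correlations quoted anywhere are conditional on the generating
  distribution; they are not a property of the estimator alone.
- The random-choice threshold depends mildly on the (configurable) walk and
  magnitude settings; treat reproduced thresholds as approximate.
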