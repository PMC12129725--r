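---
title: "Hierarchical reinforcement-learning models of four-armed bandit behaviour"
author: "banditrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical reinforcement-learning models of four-armed bandit behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and the model family

The package analyses choice behaviour in a four-armed bandit task in which
each of four cues carries an independent, slowly drifting probability of
winning a token (coded `win` in {0, 1}) and, independently, of losing one
(coded `loss` in {0, -1}). A session is 240 trials in four runs. Because
both outcome streams drift, subjects must keep learning about rewards and
punishments separately, which is what makes the task informative about
reward versus punishment processing in chronic-pain cohorts.

Five delta-rule learning models are implemented. All of them track a
reward value `Qr` and a punishment value `Qp` per cue, both starting at
zero, and choose through a softmax on the summed value `Qr + Qp`:

* **Prediction errors.** The reward prediction error on the chosen cue is
  `delta_r = R * win - Qr[chosen]`, and likewise
  `delta_p = P * loss - Qp[chosen]`. The sensitivities `R` and `P`
  (dimensionless, 0-30) scale the *outcome* entering the comparison, so
  `Qr` tracks the sensitivity-scaled reward rate. This is the convention
  of the hierarchical-Bayesian toolchains used for this model family, and
  it is the only reading under which typical fitted values (sensitivities
  above 10 with learning rates near 0.7) give stable value dynamics; the
  alternative reading, in which the sensitivity multiplies the whole
  error, makes the effective learning rate `lr * R` explode for exactly
  those values.
* **Updates.** `Qr[chosen] += lr_r * delta_r` and
  `Qp[chosen] += lr_p * delta_p`. Models 1-2 couple the rates as
  `lr_r = alpha + beta`, `lr_p = alpha - beta`; models 3-5 treat them as
  free parameters. Internally the package always parameterizes
  `(lr_r, lr_p)` on the unit square, which is algebraically identical and
  always admissible, and reports `alpha = (lr_r + lr_p) / 2`,
  `beta = (lr_r - lr_p) / 2` for coupled models. A consequence worth
  knowing: models 1/3 and 2/4 then share likelihood *and* priors, so
  out-of-sample comparison can separate the decay and lapse tiers but
  regards 1-vs-3 and 2-vs-4 as ties up to Monte-Carlo noise.
* **Decay** (models 1 and 3): every `Q` is multiplied by `1 - d` at the
  start of each trial, a forgetting process with rate `d` in [0, 1].
* **Lapse** (models 1-4): the softmax probabilities are mixed with a
  uniform component, `p * (1 - xi) + xi / 4`, so `xi` in [0, 1] is the
  probability mass of value-independent choices.

The per-trial order is decay, policy, prediction errors, update; the decay
equations reference the previous trial's values, i.e. forgetting precedes
the trial. Q-values are carried across run boundaries by default (the four
runs are contiguous blocks of one session); `reset_runs = TRUE` re-zeroes
them for sensitivity analyses. Softmax evaluation subtracts the maximum
before exponentiating and probabilities are floored at 1e-12 before
logging.

# Hierarchical estimation

`fit_bandit()` estimates each model per group with a joint posterior over
group hypermeans, group hyper-SDs and subject-level parameters. Priors
follow the conventions of the field's toolchains: each parameter is
mapped from the real line by a probit (`pnorm`) transform — scaled by 30
for the sensitivities — with Normal(0, 1) hypermean and half-Normal(0, 1)
hyper-SD priors. Sensitivity estimates reported for this task sit well
inside [0, 30].

Sampling is by the No-U-Turn sampler, implemented in C++ with analytic
gradients of the trial-loop likelihood (forward-mode accumulation through
the Q recursion). Details that mattered in practice:

* **Centered parameterization by default.** With 240 trials per subject
  the subject-level likelihood is strong, so the funnel appears in the
  *non-centered* form; the centered form (subject parameters sampled
  directly, hyperparameters conditionally) mixes far better here.
  `parameterization = "noncentered"` is available for sparse-data uses.
* **Data-informed initialization.** The likelihood has a wide plateau at
  `R = P = 0` (uniform policy). Chains start near the penalized-ML
  solution (`method = "map"`), which is computed per subject by graded
  smoothing — a temporarily fixed lapse bounds the gradients — from
  several starts with a Nelder-Mead polish.
* **Adaptation.** Diagonal mass seeded from the curvature at the
  initialization point, then re-estimated over doubling warmup windows;
  dual-averaging step size towards 0.85 acceptance with a floor of 1e-3
  (a floor converts pathological step-size collapse into occasional
  rejected divergent subtrees). Defaults: 4 chains, 1000 warmup, 2000
  kept draws per chain; the examples and tests use 2 chains and a few
  hundred draws.
* **Diagnostics.** Split-half R-hat and effective sample size per
  hyperparameter, divergence fraction, and a single `ok` flag
  (R-hat <= 1.05, divergences <= 5%). A failed pass is retried with a
  shifted seed (keeping the best attempt); failure is still reported,
  never silent.

The deterministic fallback `method = "map"` (penalized ML per subject,
moment-matched hyperparameters) is used for initialization and for fast
smoke tests; HMC is the reference path.

Group-level summaries report, per draw, the probit-transformed hypermean
("hypermean" scale, the Table-style location estimate) and optionally the
model-implied population mean ("popmean", integrating the subject
distribution by Gauss-Hermite quadrature). Derived `alpha`/`beta` and the
composite learning rates are computed per draw, which is why a reported
composite need not equal the sum of separately reported components — the
same aggregation ambiguity exists in published tables of this model
family.

# Model comparison and group contrasts

`bandit_loo()` computes the expected log pointwise predictive density by
Pareto-smoothed importance sampling over the per-trial log-likelihood
matrix (the LOO unit is the trial, pooled across subjects; a subject-level
aggregation is a matter of summing the pointwise columns). The largest 20%
of importance ratios per trial are replaced by generalized-Pareto order
statistics (Zhang-Stephens fit, weak shape prior); the shape diagnostic is
reported and a flag is raised when more than 10% of trials exceed 0.7.
`compare_models()` ranks by LOOIC (= -2 ELPD) and reports, against the
best model, the ELPD difference, its standard error computed from the
pointwise-difference vector (`sqrt(n * var(diff))`), and the sigma effect
(difference / SE); the best model's sigma is blank.

`group_difference()` contrasts two independently fitted groups. Draws are
paired through a seeded random *involution* (a self-inverse index
pairing): exchangeability of independently fitted draws makes any pairing
valid, seeding makes it reproducible, and involutivity makes the operation
exactly antisymmetric in its arguments. The 95% interval is the highest
density interval (shortest interval at the mass), and a difference is
flagged when the interval excludes zero.

# The synthetic-data module

`generate_schedule()` draws the win and loss probabilities of the four
cues as independent Gaussian random walks (step SD 0.02) reflected into
[0.2, 0.8], from separate named RNG streams. The step size and bounds are
not published for the original task; these defaults keep outcomes
stochastic yet learnable over 240 trials, and are configuration knobs.
`simulate_agent()` plays a model forward (decay, sampled choice, sampled
outcome, update) with onsets on a fixed 6-s grid so regressor export can
be exercised. `simulate_cohort()` draws subject parameters from
independent normals per parameter on the constrained scale — defaults are
the published patient ("arthritis") and control group-level estimates,
including the punishment-sensitivity gap 9.953 - 5.778 = 4.175 —
rejection-resampled into the admissible ranges. Note the rejection step
truncates the control punishment-sensitivity distribution at zero, which
raises its realized mean and shrinks realized gaps to roughly 3.7 on
average.

`generate_parcel_timeseries()` plants a connectivity hub: every parcel is
unit Gaussian noise, and the hub plus a set of linked parcels additionally
load on a shared signal (the hub 1.5x more strongly, so the planted block
centres on it). `generate_clinical_scores()` mixes a standardized
centrality vector with noise to hit a target correlation in expectation.

What these generators do *not* emulate: haemodynamics, scanner noise
spectra, motion, autocorrelated BOLD noise, session effects, or any
behavioural process outside the model family (satiation, position biases,
reaction-time coupling). Passing recovery tests therefore demonstrate
that the estimation machinery is correct and calibrated under the model,
not that the model captures every feature of real subjects.

# The connectivity stage

Task-run time series are summed elementwise (making them comparable with
a single rest run), correlated (Pearson), and binarized at a 10% link
density by keeping the `round(0.10 * n * (n-1) / 2)` strongest edges —
1611 edges for 180 parcels. Ranking is by signed correlation by default
(binarized functional networks conventionally use the most-positive
edges); `absolute = TRUE` ranks by magnitude. Ties at the cutoff break by
lexicographic node order, making the graph deterministic. Five nodal
centralities are computed: degree; eigenvector (power iteration on
`A + I`, tolerance 1e-10, unit-maximum normalization; the unit shift
prevents oscillation on bipartite components); betweenness
(shortest-path pair fractions); closeness (within-component closeness
scaled by the reachable fraction, so disconnected graphs are
well-defined); and load (equal-split packet routing along shortest paths,
pairs counted once).

Centrality-versus-clinical-score screens use the default two-sided Bayes
factor for a Pearson correlation: the exact sampling distribution of r
(Gaussian-hypergeometric form, evaluated by series) integrated over a
symmetric stretched-beta prior on the population correlation (width 1 by
default) by adaptive quadrature. Under equal prior odds,
`P(H1 | data) = BF / (1 + BF)`; the posterior error probabilities are
ranked and the q-value of the i-th test is the cumulative mean of the
first i PEPs; tests with q below the threshold (default 0.01) are
retained. The log-Bayes-factor base is configurable because published
"logBF10" values in this literature are ambiguous between natural log and
log10; no claim is made to reproduce any specific published screen.

A calibration note: at n = 30 and a planted correlation of 0.6 the Bayes
factor is around 30-100, i.e. a PEP of 0.01-0.03, which straddles the
conservative 0.01 FDR threshold. Detection of such an effect at that
threshold is therefore intrinsically borderline — roughly a coin flip per
replicate — independent of implementation quality. The acceptance tests
record this honestly rather than easing the threshold.

# Choices made at reduced scale

Hierarchical fits in the test-suite and acceptance script run at 12
subjects per group, 2 chains, and 150-500 post-warmup draws per chain;
these are the package's reduced study scales for recovery, contrast and
model-recovery simulations, chosen so that the full suite completes on a
single CPU while the fits still pass their diagnostics. Two findings at
this scale deserve explicit statement:

* Detecting the planted punishment-sensitivity group gap of ~4.2 at 12
  subjects per group is underpowered: the published group-difference
  interval at 28-29 subjects per group implies a posterior SD of ~1.7 for
  the difference, which scales to ~2.6 at 12 per group, i.e. roughly
  35-40% power — before accounting for truncation shrinkage of the
  realized gap. The group-contrast power check reflects this; its null
  calibration (no false detections when both groups share parameters)
  passes.
* Sensitivity parameters carry a mild finite-sample upward bias along the
  sensitivity-up/learning-rate-down likelihood ridge, and the hypermean
  prior (centred at 15 on the constrained scale) pulls small cohorts the
  same way. Hypermean intervals remain calibrated; point estimates
  should be read with this in mind.

# Regressor export and file formats

`export_regressors()` turns a latent trace (typically computed at
group-mean fitted parameters, the noise-minimizing convention) into six
3-column event tables per run — reward outcome, punishment outcome,
reward and punishment prediction error at the outcome onset, plus cue and
keypress tables of no interest — and `write_regressors()` writes them as
headerless whitespace-delimited text. Behaviour tables are CSV/TSV with
columns `subject, group, run, trial, choice, win, loss` and optional
onsets, validated strictly on read (`read_behaviour()`); `run_pipeline()`
orchestrates the full synthetic study from one seeded configuration and
writes comparison/contrast/screen CSVs plus a JSON run manifest.
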