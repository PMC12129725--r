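# banditrl

Reward and punishment learning in a four-armed bandit task, analysed the
way computational-psychiatry studies of chronic pain analyse it: five
hierarchical reinforcement-learning models fitted by Hamiltonian Monte
Carlo, compared by out-of-sample predictive density (PSIS-LOO), contrasted
between groups by posterior highest-density intervals, and — for the
neuroimaging arm — a brain-network centrality screen with default
Bayes-factor correlations corrected by a Bayesian false-discovery-rate
procedure. A synthetic-data module generates every input with known
ground truth, so the whole pipeline is testable without any participant
data.

## The models

Each of four cues carries independent, slowly drifting win (0/1) and loss
(0/−1) probabilities over 240 trials. All models track per-cue reward and
punishment values and choose by softmax on their sum,

```
delta_r = R * win  - Qr[chosen]        # reward prediction error
delta_p = P * loss - Qp[chosen]        # punishment prediction error
Qr[chosen] += lr_r * delta_r           # lr_r = alpha + beta  (models 1-2)
Qp[chosen] += lr_p * delta_p           # lr_p = alpha - beta  (models 1-2)
P(i) = softmax(Qr + Qp)(i) * (1 - xi) + xi/4
```

with reward/punishment sensitivities `R`, `P` scaling the outcomes,
coupled (`alpha ± beta`, models 1–2) or independent (models 3–5) learning
rates, a decay (forgetting) rate `d` on all values (models 1, 3), and a
lapse probability `xi` mixing uniform choice into the policy (models
1–4). Parameters are estimated hierarchically per group (probit
transforms, Normal(0,1) hypermeans, half-Normal(0,1) hyper-SDs,
sensitivities bounded by 30) with a No-U-Turn sampler written in C++ with
analytic likelihood gradients. See the methods vignette
(`vignettes/bandit-models.Rmd`) for the science and the numerical
choices.

## Worked example

Simulate a 12-subject cohort from the full model (model 1) at the
published patient-group parameter magnitudes, then re-fit it:

```r
library(banditrl)
sim <- simulate_cohort(model = 1, n_subjects = 12, seed = 42,
                       group = "arthritis")
fit <- fit_bandit(sim$data, model = 1, chains = 2, warmup = 400,
                  iter = 400, seed = 7,
                  control = list(max_depth = 8, min_step = 0.003,
                                 retries = 2))
print(fit)
```

```
Hierarchical bandit fit (model 1, hmc), group 'arthritis'
  12 subjects, 2880 trials total
  2 chains x 400 draws (+400 warmup)
  max split-Rhat 1.120, divergence fraction 0.040  ** DIAGNOSTICS FAILED **
  parameter    mean     sd hdi_lower hdi_upper
1         R 20.2253 4.7745   12.1565    29.549
2         P 13.3647 3.7937    7.6297    20.938
3      lr_r  0.7509 0.0782    0.5954     0.895
4      lr_p  0.8141 0.1351    0.5648     0.999
5         d  0.7014 0.0692    0.5891     0.846
6        xi  0.0883 0.0286    0.0184     0.134
7     alpha  0.7825 0.0861    0.6302     0.932
8      beta -0.0316 0.0691   -0.1487     0.107
```

The generating means were `R = 12.6`, `P = 9.9`, `lr_r = 0.73`,
`lr_p = 0.54`, `d = 0.59`, `xi = 0.10`: decay and lapse are recovered
tightly, the learning rates reasonably, and the sensitivities sit high in
wide intervals that still cover the truth — sensitivities are the weakly
identified direction of this model family at 12 subjects (a likelihood
ridge trades sensitivity against learning rate). Note the honest
diagnostics line: two short demonstration chains trip the strict
split-R-hat bar of 1.05; the defaults (4 chains, 1000 warmup, 2000 draws)
are the production setting. `summary()`, `coef()`, `predict()`,
`residuals()`, `simulate()` and `plot()` work as for any fitted-model
object; `bandit_loo()` and `compare_models()` rank models;
`group_difference()` and `group_contrast()` compare two fitted groups by
95% HDI; `export_regressors()`/`write_regressors()` emit FSL-style
3-column event files; `correlation_matrix()`, `threshold_to_density()`,
`centralities()` and `centrality_screen()` run the connectivity stage;
`run_pipeline()` drives everything from one seeded configuration.

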