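---
title: "Models and methods in discountr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in discountr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`discountr` analyses intertemporal-choice experiments in which the same
subjects choose between a fixed immediate reward and a larger delayed
reward across tasks that differ in time-horizon (seconds vs. days vs.
weeks) and modality (verbal offers vs. experiential, sound-cued offers).
This vignette is the package's account of the models it fits, the
simulator it tests itself with, and the numerical and design choices a
user should know about.

## The choice model

Each offer pits a sooner option (magnitude $V_S$, delay 0) against a later
option (magnitude $V_L$, delay $T$ in the task's native unit). Subjective
value follows hyperbolic discounting,

$$U = \frac{V}{1 + kT},$$

with discount rate $k$ (units 1/time). We work with $\log k$ throughout
because discount rates are approximately log-normal across people. The
probability of choosing the later option is a softmax (logistic) in the
utility difference with decision noise $\tau$:

$$P(\text{later}) = \frac{e^{U_L/\tau}}{e^{U_L/\tau} + e^{U_S/\tau}}.$$

Two useful identities: a reward is worth exactly half its face value when
$kT = 1$, so the half-value delay is $1/k$ (`half_value_delay()`); and
because $k$ carries units of 1/time, re-expressing a per-second rate per
day adds $\log 86400 = 11.37$ to $\log k$ (`convert_rate_units()`,
`unit_shift_prediction()`). The latter is the shift one would observe if
subjects ignored delay units entirely, which the shift/scale and
days-vs-weeks analyses test against.

Model comparison considers four classes (`standard_model_classes()`):
hyperbolic or exponential utility ($U = V e^{-kT}$, the standard
constant-hazard form) crossed with the shift-invariant softmax or a
scale-invariant matching rule
$P(\text{later}) = U_L^{1/\tau} / (U_L^{1/\tau} + U_S^{1/\tau})$.
The matching rule is implemented as the Luce power form so that $\tau$
plays the same noise role in both rules. Optional switches add utility
curvature ($V \mapsto V^\alpha$) and reward scaling ($V \mapsto \rho V$),
both applied to magnitude before discounting, both fit through log-links.

## Per-subject estimation

`fit_subject_mle()` minimises the negative Bernoulli log-likelihood over
$(\log k, \log\tau, \ldots)$ with a multi-start Nelder-Mead search (starts
spread over $\log k \in [-10, 0]$, jittered; bounds of plausibility
$\log k \in [-12, 2]$, $\log\tau \in [-3, 3]$) followed by a BFGS polish.
Standard errors come from the inverse observed information. Choice
probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ inside the
likelihood so that one surprising choice cannot produce an infinite
objective.

Subjects who always (or never) chose the later option carry no information
about $k$; they are flagged `insensitive` and not fit, mirroring the
exclusion of such subjects from model fitting. Subjects *close* to
one-sided have finite but enormous MLEs with huge standard errors; any
analysis that correlates estimates across tasks should restrict to
well-identified cells (we use `logk_se < 1` in our own tests) or use the
hierarchical posteriors, which shrink these cells sensibly.

Leave-one-trial-out cross-validation (`loo_cv_score()`) refits the model
$n$ times with one trial held out. Each refit warm-starts at the
full-data optimum with a single Nelder-Mead restart; this is a deliberate
trade-off — a full multi-start per fold would be hundreds of times slower
and changes nothing in practice because removing one trial moves the
optimum microscopically. BIC is $p\ln n + 2\,\mathrm{NLL}$;
`compare_model_classes()` averages it across subject-task cells, reports
the count of cells "well described" (McFadden pseudo-$R^2 \ge 0.2$, a
threshold we chose since no numeric criterion is standard), selects the
lowest mean BIC, and breaks ties toward fewer parameters.

## The hierarchical model

`fit_hierarchical()` is the central computation: a Bayesian hierarchical
version of the softmax-hyperbolic model for all subjects and tasks at
once, mirroring the mixed-effects formula
`choice ~ inv_logit((V_L/(1+exp(logk)*T) - V_S)/tau)` with
`logk ~ task + (task | subject)` and `log tau ~ task + (1 | subject)`.
Population levels per task sit over correlated per-subject $\log k$
deviations (one per task, jointly normal) and a single per-subject noise
deviation. Delays stay in each task's native units; cross-task unit
conversions are applied explicitly afterwards and never inside the fit.

Sampling is Gibbs/slice via JAGS (`rjags`), 3 chains, 600 adaptation /
800 burn-in / 1200 kept draws per chain by default. Two implementation
choices matter:

* **Hierarchical centring.** Subject-level $\log k$ is sampled directly
  around the population mean (`lk[s,] ~ dmnorm(mu_logk, Omega)`) rather
  than as zero-mean deviations added to it. With informative per-subject
  data the centred form makes the population-mean update near-conjugate;
  in our benchmarks the uncentred form needed minutes per fit and still
  failed $\hat R < 1.05$, while the centred form reaches $\hat R \approx
  1.01$ in seconds. Zero-mean deviations are reported as derived
  quantities.
* **Priors.** Population $\log k$: Normal(-3, 3) per task, wide enough to
  cover the range reported for tens of thousands of subjects
  ($\log k \in [-8.75, 1.4]$). Population $\log\tau$: Normal(0, 1);
  subject $\log\tau$ SD: half-Normal(0, 1). The covariance of subject
  $\log k$ deviations gets an inverse-Wishart prior (identity scale,
  $T+1$ df), which makes each pairwise correlation marginally uniform.
  An LKJ-plus-half-Normal decomposition would be marginally preferable
  but is not expressible in JAGS's graph language; the Wishart's mild
  shrinkage of the per-task SDs toward 1 is visible only for very small
  cohorts.

Convergence is gated on split-$\hat R \le 1.05$ and effective sample size
over all population-level parameters; downstream operations
(`posterior_summary()`, `evidence_ratio()`, `bayes_r2()`,
`shift_scale_report()`) refuse unconverged fits unless `force = TRUE`.

The **reward-scaling expansion** (`fit_reward_scaling_model()`) multiplies
both magnitudes by $\rho = e^{\log\rho}$ with one level per time-horizon
(short = seconds tasks, long = day/week tasks) and per-subject deviations,
priors centred on $\rho = 1$ (Normal(0, 0.5) population, half-Normal(0,
0.5) subject SD). Within a subject, $\rho$ and $\tau$ trade off along a
ridge (only $\rho/\tau$ per horizon is strongly identified), so this model
mixes more slowly; expect to need several-fold longer chains than the
base model, and rely on the priors for the split. Model comparison uses
`kfold_ic()`: subjects-and-task-stratified folds (every training set
retains all subjects), held-out log posterior predictive density summed
and scaled by $-2$. Pairwise `kfold_compare()` gets its standard error
from the pointwise contributions, which is only valid on identical data
and fold assignment.

`evidence_ratio()` reports posterior odds $P(\text{hypothesis}) /
P(\text{alternative})$ for one-sided comparisons, capped at the draw
resolution. `bayes_r2()` is the posterior-predictive variance ratio
$\mathrm{var}(p) / (\mathrm{var}(p) + \overline{p(1-p)})$ per draw.

## The simulator

`simulate_cohort()` generates study-shaped data so every downstream stage
is testable without any external data. What it emulates:

* **Offer schedules** (`make_offer_schedule()`): 5 delays ({3, 6.5, 14,
  30, 64} in task units) crossed with 5 magnitudes ({1, 2, 5, 8, 10}
  coins) against a fixed sooner option of 4 coins now; magnitude-blocked
  with block lengths jittered $\pm 1$ trial; delays cycled in random order
  within blocks; dominated "smaller-later" offers (magnitudes 1-2) receive
  25% of trials in the non-verbal task and 10% in verbal tasks, split
  equally between the two magnitudes, with all larger-later offers equally
  likely. Defaults: 200 trials for NV spread over three sessions, 170 for
  each verbal task over two sessions — 170 rather than the average 160 so
  that the jitter can never push a subject below the 160-trial floor, and
  so the smaller-later share is exactly 0.10 before jitter.
* **Population structure** (`sample_population()`): per-task subject
  $\log k$ jointly normal with means (-3.2, -3.49, -3.95) for (NV, SV,
  LV) — the posterior means reported for the three tasks — SDs (1.1, 0.8,
  1.2) and cross-task correlations (0.8 NV-SV, 0.6 SV-LV, 0.4 NV-LV),
  chosen once to mirror the observed ordering of scales and reliabilities;
  noise geometric means (1.5, 0.8, 0.8) with a shared subject deviation
  (SD 0.3 in logs), reflecting the higher perceptual noise of the
  non-verbal task. Reward scaling defaults to exactly 1 (no
  heterogeneity); tests that need it switch on `sd_log_rho`.
* **Day/week control tasks** (DV, WV): five-point delay grids spanning
  1-64 days and 1-35 weeks (the exact grids are not printed anywhere;
  ours are geometric-ish spans of the stated ranges).

What it does **not** emulate: learning stages, lapses and first-order
violations from inattention (simulated agents only produce dominated
choices through decision noise), reaction times, session wall-clock
effects, and any true early-trial adaptation. Passing recovery tests
therefore shows the estimators are correct for data satisfying the model,
not that the model is right for real subjects.

## Reliability and context analyses

Cross-task reliability uses Pearson (Fisher-z CI) and Spearman
(bootstrap CI) correlations. Because estimation noise attenuates
correlations even for perfectly rank-stable subjects,
`attenuation_ceiling()` simulates task pairs whose generating $\log k$
share a single subject factor, runs the same estimator on both, and takes
the mean attainable Spearman correlation (default 500 replicates) as the
ceiling; `corrected_rank_correlation()` divides the observed value by it,
capping at 1 with a flag. Dependent overlapping correlations are compared
with Steiger's $\bar z^*$ and Williams' $t$, implemented from the
formulas and validated in the test suite against a subject-swap
permutation oracle. Bootstrap tests follow the resample-and-locate-zero
construction (10,000 resamples by default) with a sign-flip permutation
for paired comparisons; at small samples the percentile construction is
mildly conservative, which our calibration checks quantify at $n$ of a
few dozen.

The horizon-vs-modality decomposition (`gap_variance_mixed_model()`)
regresses per-subject, per-task $\log k$ on `days` (true only for the
long task) and `verbal` (true for both verbal tasks) with a subject
random intercept, fit by ML (not REML) so likelihood-ratio tests on the
fixed effects are valid; each factor is judged by dropping it.

The adaptation analysis converts each offer into a utility difference
$\Delta U$ under the subject's fitted task-specific $k$
(`delta_utility()`, first 4 trials of a task flagged "early" — the
threshold is exposed as `early_max`) and fits a mixed logistic model with
per-subject intercept and $\Delta U$ slope (`adaptation_glmm()`,
Laplace-approximate ML via lme4; `nAGQ = 0` available for bulk
simulation). Adaptation is tested by the 2-df LR chi-square against the
reduced model without the early terms. Where a subject enters a task
repeatedly within a session, the early flag counts trials from the first
entry per task (trial index within task), not per block entry.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the
caller's RNG state; a single seed fixes an entire simulated cohort, and
per-chain MCMC seeds derive from the configuration seed. The package's
own acceptance checks run at reduced but honest scales chosen once:
population recovery on 20 cohorts of 20 subjects x 60 trials x 3 tasks;
reliability ordering on 20 cohorts of 63 subjects at full trial counts;
K-fold comparison with k = 3 on 12 subjects x 160 trials (k defaults to
10 in `kfold_ic()`); calibration of the bootstrap and adaptation LR tests
on 1,000 null simulations each. The vignette-level rationale for each is
simply that these are the smallest sizes at which the corresponding
property is expected to hold with comfortable margin under the generator
defaults.

## Known limitations

* The Gibbs sampler's reward-scaling expansion is prior-dependent along
  the $\rho$-$\tau$ ridge; population $\rho$ levels should be read as
  regularised, not sharply identified.
* Quasi-hyperbolic ($\beta$-$\delta$) and other discounting families,
  lapse mixtures, and probit links are out of scope.
* The insensitive-subject rule (fraction later exactly 0 or 1) is the
  operationalisation of a qualitative exclusion; near-one-sided subjects
  pass it and must be handled through identification checks.
* Corrected correlations inherit Monte-Carlo error from the ceiling
  simulation; report the ceiling alongside the corrected value.
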