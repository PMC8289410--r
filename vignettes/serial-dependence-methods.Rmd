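---
title: "Dissociating prior-stimulus and prior-choice biases in 2AFC decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating prior-stimulus and prior-choice biases in 2AFC decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

## The problem

In two-alternative forced-choice (2AFC) discrimination, current decisions
are not independent of the recent past. Two distinct mechanisms pull in
opposite directions: *adaptation* repels perception away from recently seen
stimuli, while a *consistency bias* attracts decisions toward recently made
choices. Aggregate measures of serial dependence — such as the shift of the
point of subjective equality (PSE) between conditions with left- versus
right-biased recent history — confound the two: a negative stimulus effect
and a positive choice effect can partially or wholly cancel, so a small
aggregate shift does not imply small underlying biases. This package
implements, end to end, an analysis that dissociates the two influences
with a choice-history logistic regression, together with a closed-loop
generator of the experimental paradigm that produced such data, so every
step can be validated by parameter recovery on synthetic observers.

## The paradigm generator

Each trial of the location-discrimination paradigm presents a random number
of "prior" circles whose horizontal positions are drawn from a biased
normal distribution, followed by one unbiased "test" circle. Every stimulus
is discriminated (left/right of center). The generator reproduces this
structure exactly:

* **Prior count.** The number of priors per trial is a discrete normal on
  the integers 1–9 (mean 5, SD 2). We normalize the Gaussian density over
  the support, `pmf(k) ∝ exp(-(k-5)²/8)`; rounding truncated continuous
  draws would be an equally defensible construction, and we do not claim
  ours is the original implementation — the resulting pmf differs only in
  the third decimal.
* **Prior locations.** Normal with mean ±3.82° and SD 3.82°. Because the
  mean equals the SD, about `r round(100 * pnorm(-1), 1)`% of priors fall
  on the side opposite the bias (Φ(−1)), so the bias is statistical, not
  deterministic.
* **Test staircase.** Test magnitudes follow a one-up/two-down staircase:
  start 6.36°, multiply by 0.6 after two successive correct responses,
  divide by 0.6 after an error, cap 25.46°. Steps are multiplicative, so
  the magnitude can never reach zero; magnitudes below 0.05° are worth
  inspecting as a convergence diagnostic but are not clipped. The rule
  targets the performance level p with p² = 0.5, i.e. ~70.7% correct,
  which `staircase_convergence()` verifies by simulation. Only test
  responses drive the staircase; prior discriminations never do.
* **Interleaving.** One 100-trial staircase per prior type (left/right),
  interleaved pseudo-randomly. No interleaving algorithm is canonical; we
  draw each successive trial without replacement from the remaining trial
  budgets of the two staircases, which makes the type sequence exchangeable.
* **Timing is not simulated.** The generator emits event sequences only —
  no stimulus durations, fixation, or response times.

A simplified heading-style variant (`mode = "heading_n1"`) produces single
staircase discriminations without designed priors; there, the "prior type"
of a trial is defined after the fact by the choice on the previous
discrimination.

## The synthetic observer

The analysis needs ground truth, so the generator includes observers that
*are* the fitted model, inverted. The probability of a rightward choice is

$$p_t = \lambda + (1 - 2\lambda)\,\frac{1}{1 + e^{-z_t}}, \qquad
z_t = \beta_0 + \beta_{curr}\,s_t + \beta_{ps}\,\bar s_{prev}
      + \beta_{pc}\,\bar c_{prev},$$

with stimuli on the RMS-normalized scale, choices coded +1/−1, and a
symmetric lapse mixture λ. Two conventions needed deciding:

* **Generative stimulus scale.** The fitted model normalizes by the RMS of
  all stimuli the participant actually saw; in a closed loop that RMS is
  unknown until the session ends. The observer therefore uses a *nominal*
  RMS fixed per configuration: the prior term analytically
  (E[s²] = µ² + σ²), the test term by Monte Carlo of the staircase driven
  by a reference cumulative-Gaussian observer with a 3° threshold (a
  typical value for this task), weighted 5:1 (the expected ratio of prior
  to test discriminations). The residual mismatch between nominal and
  realized RMS is below ~2% and is absorbed into recovery tolerances.
  Whether real observers weight raw or normalized stimulus history is not
  something this choice asserts — it is the simulator's convention.
* **History of prior responses.** Under the default `per_trial_priors`
  horizon, responses to prior stimuli are generated from baseline +
  current stimulus only, and the trial's priors enter the test response as
  averages — mirroring exactly the structure the fitted model assumes. The
  `n_back_1` horizon instead conditions every discrimination on the single
  preceding one (the heading-style generative model).

Default cohort parameters (`cohort_spec()`) emulate the group contrast of
interest: mean prior-choice weight 0.6 (ASD) vs 0.3 (control), SD 0.15,
n = 18/20; current-stimulus weight 2.5 ± 0.5 on the normalized scale
(which puts staircase convergence near 2° and fitted thresholds in the
2–4° range typical of the task); prior-stimulus weight −0.15 ± 0.1 (small
adaptation); lapse 0.03 ± 0.015, truncated to [0, 0.25].

## Psychometric fitting

Choice curves are fit per participant, condition and prior type with the
lapse-rate cumulative Gaussian
$\phi(s) = \lambda + (1-2\lambda)F(s;\mu,\sigma)$ by bounded maximum
likelihood: µ ∈ [−45, 45]°, σ ∈ [0.05, 100]°, λ ∈ [0, 0.25], L-BFGS-B from
a fixed multi-start grid (PSE starts at the stimulus quartiles, thresholds
at 0.5/2/8/32°, lapse at 0.01/0.1), so the fit is deterministic given the
data. A single symmetric λ is used, as in the model equation. The original
analyses used the psignifit toolbox; its priors and bounds are not public,
so per-participant numerical equality with a psignifit fit is not a goal —
group-level properties are, and those are what the tests assert.

Goodness of fit is the likelihood-ratio pseudo-R²,
$R^2_L = 1 - D_{fitted}/D_{null}$. Deviances are twice the log-likelihood
gap to the saturated model, with the saturated model fitting each stimulus
*level* its empirical rightward proportion — staircase magnitudes repeat
exactly, so grouping is meaningful, and this matches how grouped
psychometric software computes deviance. (Computing deviances per trial
instead, i.e. against a saturated log-likelihood of zero, caps $R^2_L$
near 0.25 on staircase data even for ideal observers and would empty the
screen.) The null model is a single constant-probability Bernoulli at the
empirical rightward rate (no lapse parameter), on the same observations.
Participants are kept only if *every* curve has $R^2_L > 0.5$ (strict);
under the default generator, faithful observers score ≈ 0.6–0.95 and
stimulus-blind ones ≈ 0.
The aggregate history effect is
$\Delta PSE = PSE_{left} - PSE_{right}$; positive values mean attraction
toward the prior direction. Thresholds are averaged on the natural-log
scale (they are non-negative and scale multiplicatively); lapse-rate
comparisons pool all prior and test discriminations per condition; the
model-free check uses percent correct on "easy" trials, |s| above the
participant-condition's 66th percentile. Stimuli at exactly s = 0 have no
correct answer: they never arise from the generator (staircase magnitudes
are positive) and, if present in imported data, are excluded from
percent-correct computations while remaining in the fits.

## The choice-history model

For the primary analysis, one design row per test trial carries the
current normalized stimulus, the mean of the trial's prior stimuli, and
the mean of the trial's prior choices; the heading-style variant uses the
single previous discrimination. The lagged variant treats all
discriminations as one sequence and uses the five preceding choices as
separate regressors (with lagged stimuli available for the preliminary
two-lag check of both factors; only choice lags proved informative there,
so the five-lag model carries choice lags plus the current stimulus and
intercept).

Fitting is unregularized Bernoulli ML via Newton-Raphson, started at zero
with gradient-norm tolerance 1e-8 and a 200-iteration cap — the NLL is
convex, so when a finite optimum exists this finds it, and a test verifies
the fit is never beaten by exhaustive grid search on small designs.
Perfect separation or collinearity (diverging coefficients, singular
Hessian) is flagged and the fit excluded rather than regularized, keeping
estimates comparable across participants. RMS normalization makes all
fitted betas invariant to the raw stimulus unit.

For heading-style data with interleaved conditions the n = 1 prior is the
chronologically previous discrimination, whether or not it belonged to the
same condition; with interleaving the previous trial is usually a
different condition, and the alternative (previous same-condition trial)
would skip arbitrary temporal gaps, so the chronological convention is the
one we adopt and document.

## Group statistics

Group contrasts use Student's pooled-variance t (df = n₁ + n₂ − 2, the df
accounting consistent with 18 + 20 − 2 = 36), two-tailed. The two history
coefficients — the only confirmatory contrasts — are corrected by
multiplying p by two (Bonferroni over two tests), with 97.5% confidence
intervals in lieu of 95%; β₀ and β_curr are sanity checks and carry raw
p-values, as do ΔPSE tests (separate datasets, one hypothesis each).
Cohen's d intervals invert the noncentral-t CDF (checked in the tests
against brute-force grid inversion). Pearson correlations report df =
n − 2. Omnibus MANOVA/mixed-ANOVA and Bayes factors are deliberately out
of scope; the report says where to take the participants table if those
are wanted.

## What the synthetic data can and cannot show

The generator reproduces the paradigm's trial structure, stimulus
statistics, staircase dynamics and the decision model's history terms, plus
lapses. It does not emulate learning or drift across a session, response
times, motor errors distinct from lapses, or any stimulus-duration
effects. Passing recovery tests therefore shows the *analysis* is correct
and well-calibrated for observers of this class — not that real observers
obey the model. Three empirical facts from the validation runs are worth
stating plainly:

* **Recovery.** At 2,000 test trials per session, all four betas are
  recovered to within ±0.1 (mean over 100 replicates). At the task's
  native 200 test trials the history and bias terms are recovered without
  systematic bias, but the current-stimulus weight is inflated by ~5–6%.
  This is the well-known finite-sample bias of unregularized logistic ML
  compounded by the adaptive staircase, which concentrates stimuli near
  threshold (slope estimates from adaptive runs are biased upward; we
  follow the original analysis in applying no staircase-aware correction).
  The inflation vanishes by 2,000 trials.
* **Cancellation.** An observer with a negative stimulus weight and a
  positive choice weight tuned to offset produces ΔPSE ≈ 0 while the
  model recovers both weights with correct signs — the package's
  operational demonstration that aggregate PSE shifts confound the two
  mechanisms.
* **Power.** The averaged prior-stimulus and prior-choice regressors are
  strongly correlated (r ≈ 0.84 in simulation: both are driven by the
  trial's bias direction), which inflates the standard error of the
  choice weight to ≈ 0.45 per 200-trial session — about three times the
  between-participant SD of 0.15. Detection of a 0.3 gap in the choice
  weight at n = 18/20 with the corrected t-test therefore has
  substantially less than 80% power under these conditions; this is a
  property of the paradigm's regressor geometry, not of the fitting code,
  and it is consistent with the marginal group statistics such designs
  yield in practice. The null-cohort false-positive rate is at the
  nominal α.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use: 120 sessions for staircase
convergence (burn-in 20 trials), 10⁶ draws for the prior-location tail,
100 replicates of 2,000-trial sessions and 200 replicates of 200-trial
sessions for recovery, 50 sessions per observer for the cancellation
analysis, and 200 cohort replicates for power/calibration — sizes at which
the Monte-Carlo error is well below each assertion's tolerance. Likelihood
evaluations clip probabilities to [1e−12, 1 − 1e−12]; the psychometric
optimizer uses L-BFGS-B with `factr = 1e5`; the logistic Newton solver
declares divergence beyond |β| = 30. Ties in the easy-trial percentile use
the strict inequality |s| > q₆₆.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
cohort <- simulate_cohort(cohort_spec(), paradigm_config())
results <- run_pipeline(cohort$sessions)
print(results)
```

The report lists inclusion bookkeeping (input = analyzed + excluded), the
per-condition ΔPSE tests, and the group contrasts with the ×2 policy
applied to the two history betas only.
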