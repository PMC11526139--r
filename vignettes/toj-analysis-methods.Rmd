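---
title: "Methods: temporal order judgment analysis in tojpsych"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal order judgment analysis in tojpsych}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tojpsych)
```

This vignette is the package's own account of the science it implements:
the psychophysical observer model, the adaptive staircase, the estimators,
the permutation and Bayes-factor machinery, and the design of the
synthetic cohort generator, together with the numerical choices and their
rationale.

## The observer model

A temporal order judgment (TOJ) trial presents two stimuli from different
modalities separated by a signed stimulus onset asynchrony (SOA). The
package's coordinate convention is: **positive SOA means the condition's
reference modality physically led** (reference: audio in AT, visual in AV
and VT). The probability that the observer reports the reference modality
first is modelled as a lapse-mixed cumulative Gaussian,

$$P(\text{reference first} \mid s) \;=\; \frac{\lambda}{2} +
(1-\lambda)\,\Phi\!\left(\frac{s - \mu}{\sigma}\right),$$

with PSE $\mu$ (ms; the bias), slope $\sigma$ (ms; the precision), and
lapse rate $\lambda$. The JND is half the interquartile span of the
curve, $(x_{.75}-x_{.25})/2 = \sigma\,\Phi^{-1}(0.75) \approx 0.674\sigma$
— both forms are computed and agree to $10^{-9}$ relative (this identity
is asserted in the test suite). Note that published TOJ figures sometimes
draw the mirror-image axis (positive = reference *second*); flipping the
convention negates every PSE and leaves every JND unchanged, which a test
verifies, so the choice is a pure labelling convention.

Assumptions worth keeping in mind: a stationary observer (no learning or
fatigue within a block), symmetric lapses, and a single $\sigma$ shared
across an observer's conditions in the generator (the fitter estimates
each condition independently and does not rely on this).

## QUEST: Bayesian adaptive SOA placement

Each trial's SOA magnitude is chosen by a QUEST staircase: a discretized
posterior over the observer's temporal threshold $T$ on a grid (default
10–800 ms in 10 ms steps), initialized from a Gaussian prior (default
mean 200 ms, SD 200 ms; `prior_sd_ms = Inf` gives a flat prior) and
updated after every answered trial with the likelihood of a Weibull
response kernel on linear SOA,

$$p(\text{correct}\mid x, T) = \delta\gamma +
(1-\delta)\left\{1-(1-\gamma)\exp\!\left[-(x/T)^{\beta}\right]\right\},$$

with guess rate $\gamma = 0.5$ (two-alternative order report), assumed
slope $\beta = 3.5$, and lapse allowance $\delta = 0.01$. These kernel
constants follow the standard QUEST literature defaults and are all
exposed in `quest_config()`. The next magnitude is the posterior mean
(default; mode and quantile rules are available), snapped to the grid and
clamped to [0, 800] ms. Because likelihoods multiply, updates commute:
the posterior depends only on the multiset of (SOA, outcome) pairs, and
it remains a proper distribution after every update — both are asserted
as properties in the tests.

Adapting QUEST to a *signed* two-alternative TOJ requires a decision the
staircase literature leaves open: the staircase tracks an **unsigned**
magnitude (threshold of correct order report), and each trial's sign —
which modality actually leads — is a fair coin from the seeded stream.
Skipped trials (the observer may decline a trial they did not perceive)
are recorded with a skip flag, carry no response, never update the
staircase, and are not replaced, so a 52-trial block yields at most 52
analyzable trials. A practice gate (3–10 easy trials at 600–800 ms until
three consecutive correct) can be simulated but produces no analysis
records.

## Psychometric estimation

`fit_cumulative_gaussian()` maximizes the trial-level Bernoulli
log-likelihood
$\sum_i k_i \log \psi_i + (n_i - k_i)\log(1-\psi_i)$ with
$\psi_i = \Phi((s_i-\mu)/\sigma)$ over the aggregated proportions table.
Trial-level maximum likelihood was chosen over least squares on
proportions because it weights SOA levels by their information content
and is directly checkable against an exhaustive grid-search oracle (a
1-ms grid maximizer agrees within one grid step in the tests); a
least-squares criterion remains available via `method = "ls"` for
sensitivity analyses. Two free parameters are fitted — no lapse term —
matching the standard two-parameter Gaussian-error-function procedure.

Numerical choices: bounded L-BFGS-B from six deterministic multistarts
($\mu_0 \in \{-100, 0, 100\}$, $\sigma_0 \in \{50, 200\}$ ms), bounds
$\mu \in [-800, 800]$, $\sigma \in [1, 2000]$ ms, and $\psi$ clamped to
$[10^{-12}, 1-10^{-12}]$ before taking logs. Perfectly separated data
(an all-0 region meeting an all-1 region with no overlap) drive
$\sigma$ to its lower bound; such fits are flagged non-identifiable
(`converged = FALSE`) and their JND is reported missing rather than as a
spuriously tiny value. Fits need at least two distinct SOA levels.

Participant exclusion follows the Tukey interquartile-range rule within
each group × condition cell: JNDs outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ (type-7 linear
interpolation quantiles, the R default — the multiplier and quantile type
are not dictated by the procedure's common description, so the package
fixes them explicitly) flag the participant, and a participant flagged in
any condition is excluded from all analyses. Cells with fewer than four
members skip the filter with a warning.

## Group inference

`permutation_mixed_anova()` implements the classic split-plot
decomposition with a centered continuous age covariate. The
participant-mean stratum carries Group, Age and Group×Age against the
between-participant error ($df = N - 6$ for three groups); the
participant-centered stratum carries Condition, Condition×Age,
Group×Condition and Group×Condition×Age against the within-participant
error ($df = 2N - 12$ with three conditions). Sum-to-zero contrasts keep
the within-stratum columns orthogonal to the participant space, so the
two strata partition the total sum of squares exactly (asserted to
$10^{-8}$ relative). Effects are Type III (full vs reduced model in the
effect's stratum).

Permutation p-values use the **Freedman–Lane** scheme, the accepted
approach for covariate-adjusted permutation ANOVA: for each effect, the
reduced-model residuals in that effect's stratum are permuted (freely
across participants for between effects; condition labels within each
participant for within effects), the full-model F is recomputed, and
$p = (1 + \#\{F^* \ge F\})/(1 + n_{\mathrm{perm}})$ — so the smallest
attainable p is $1/(1+n_{\mathrm{perm}})$ and the test is valid by
construction under exchangeability. The default is 5000 permutations;
seeds are mandatory and runs are bit-reproducible. Calibration is
verified empirically: over 1000 null simulations at $n_{\mathrm{perm}} =
499$, the empirical type-I error of the Group test and of the permutation
post-hoc t lies in [0.03, 0.07] at $\alpha = 0.05$.

Generalized eta squared divides each effect's SS by itself plus **all**
error terms (both strata), the Olejnik–Algina convention, making values
comparable across between- and within-participant effects.

Post-hoc comparisons use each participant's **mean JND across the three
conditions** (condition effects are typically null in this design, and
group-level post-hocs are the target); a Welch t statistic is used since
permutation makes the reference distribution exact regardless, and small
designs switch to exhaustive enumeration automatically. Bonferroni
correction uses the family of three group pairs.

## Bayes factors

Two Bayes-factor routes corroborate the permutation results:

* `jzs_ttest_bf()` — the Jeffreys–Zellner–Siow two-sample Bayes factor
  (Cauchy prior, default scale $r = 0.707$, on the standardized effect),
  computed by adaptive quadrature of the one-dimensional g-mixture
  integral with relative tolerance $10^{-10}$; an independent oracle that
  integrates the noncentral-t likelihood against the Cauchy prior agrees
  to $10^{-4}$ relative in the tests.
* `linear_model_bf()` — model-vs-null Bayes factors for Group, Condition,
  Group+Condition and Group×Condition structure in a repeated-measures
  table, under Zellner–Siow mixture-of-g priors with an additive
  participant nuisance block. Each block has its own g with an
  inverse-gamma(1/2, $r^2$/2) mixing prior ($r = 1$ for the participant
  block, $r = 0.5$ for effect blocks, the usual random/fixed scales);
  marginal likelihoods are integrated by plain Monte Carlo over the g's
  (default 4000 draws) and the relative integration error is reported
  alongside each BF. The participant random-effect treatment is
  intercept-only — the simplest structure consistent with the design;
  random condition slopes per participant are deliberately out of scope.

A caution the tests encode: "duplicating the data moves every BF away
from 1" is *not* a theorem. Duplication doubles the F of whatever sample
effect exists, so a null-favoring BF with a small nonzero sample effect
can move toward 1; the monotone behavior holds for BF > 1 and for data
whose sample effect is exactly zero, and only those regimes are asserted.

## Symptom models

Kendall's $\tau_b$ (tie-corrected in both margins, normal approximation
with the full tie-corrected variance of S) screens each patient's mean
JND against the four clinical scales (PANSS positive and negative, YMRS,
HAM-D) and, separately, the four medication equivalents, each family
Bonferroni-corrected over 4. Healthy controls carry no scale scores and
are excluded; missing doses are dropped pairwise. The implementation is
checked against exhaustive $O(n^2)$ pair counting on random tied
instances.

The headline model is a negative-binomial GLM with log link,
`PANSS positive ~ 1 + JND` (NB2 variance $\mu + \mu^2/\theta$), fitted by
profile maximum likelihood over ($\beta_0$, $\beta_1$, $\theta$) via
`MASS::glm.nb`; $\theta$ is capped at $10^6$ with a warning when the data
are equidispersed (Poisson limit — where the estimates match a Poisson
GLM to $10^{-3}$, as tested). Effect strength is summarized by the Wald
z of $\beta_1$ and by Nagelkerke's pseudo-$R^2$,
$R^2_{CS}/(1 - e^{2\ell_0/n})$ with
$R^2_{CS} = 1 - e^{2(\ell_0-\ell_1)/n}$, against the intercept-only
negative-binomial null. Deviance residuals are the natural residual type
for normality checks on this model (the choice of residual type is
otherwise open).

## The synthetic cohort generator

`cohort_config()` defaults define the study conditions the analysis is
validated under:

* **Design**: three groups (HC 21, BD 20, SZ 21), three conditions × 52
  QUEST-placed trials on [0, 800] ms, randomized block order.
* **Demographics and scales**: ages truncated-normal on [18, 75] and sex
  ratios per group; HAM-D, YMRS, PANSS-negative/general and the four
  medication equivalents drawn truncated-normal at published
  per-group means/SDs, independent of precision; roughly 10% of patients
  have missing medication records. Scale floors are enforced (PANSS
  positive/negative ≥ 7, general ≥ 16, by resampling).
* **Psychometrics**: observer $\sigma$ truncated-normal with mean 150 ms
  (SD 40) for controls — giving a true JND near 100 ms, a realistic
  multisensory TOJ precision — and a 2× elevation (mean 300, SD 90 ms)
  for both patient groups. The elevation multiplier is a configurable
  modelling choice, not an empirical estimate: published work shows the
  patient deficit's direction but not its JND means. True PSE per
  group × condition is drawn around published cell means with a
  between-participant SD of 150 ms; that SD is chosen so the cell means
  are mutually consistent with sampling noise (their observed spread is
  what ~n = 20 cells of a 150 ms-SD population produce), matching the
  finding that PSE shows no reliable group or condition structure.
* **Symptom coupling**: PANSS-positive is drawn NB with
  $\log \mu = \beta_0 + \beta_1 \cdot \overline{\mathrm{JND}}$,
  $\beta_0 = 2.4$, $\beta_1 = 0.002$ per ms, $\theta = 8$ — the slope at
  its published estimate, and $\beta_0$ set so patient means land in the
  published 14–17 range at typical patient JNDs. The scale floor
  (resampling below 7) attenuates the recoverable slope slightly
  (~10% at these settings); the coupling test therefore asserts recovery
  at n = 1500 patients, where the 2-SE band genuinely contains the truth.
* **Skips and lapses**: default skip rate 0.007 per trial reproduces mean
  analyzable trial counts of ≈51.3–52 out of 52; lapse rate defaults to 0
  (the fitted model has no lapse term) and is available for robustness
  stress tests.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: reaction times and the 10 s response timeout,
practice-phase learning, block-order effects, attentional drift or
non-stationarity within a block, asymmetric modality-specific lapses, and
any true dependence of PSE on psychopathology. Observers are exactly
cumulative-Gaussian; real psychometric functions deviate in their tails,
so real-data σ estimates inherit a model-misfit component the synthetic
recovery rates (median relative σ error ≈ 9% at 3 × 52 trials, in the
acceptance run) do not include.

## Problem sizes and budgets

The validation suite uses sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping a full run inside a few
minutes on one core: 200 observers for psychometric recovery, 200
sessions for QUEST convergence, 1000 null datasets × 499 permutations for
type-I calibration, 100 random instances for the τ-b oracle, n = 2000 for
GLM recovery, and 40 fixed-seed cohorts for screening power/calibration.
The acceptance script runs the full default-condition study with 2000
permutations and 4000 Monte-Carlo draws per Bayes-factor model.

## Known limitations

* The permutation ANOVA follows the univariate split-plot decomposition;
  it does not implement multilevel (random-slope) alternatives, and
  sphericity is assumed for within-participant effects (permutation
  protects the p-value's validity under exchangeability, not the F's
  nominal distribution).
* `linear_model_bf` uses plain Monte Carlo over the g's; with very strong
  effects the integrand is heavy-tailed and the reported relative error
  grows — raise `n_mc` when it exceeds a few percent.
* The QUEST engine covers the classic single-threshold routine only; Psi
  or QUEST+ variants, non-stationary observers and inter-trial
  dependencies are out of scope.
* With 52 trials per block, single-condition σ estimates are noisy;
  recovery tolerances (median σ error ≤ 30% pooled over three blocks)
  reflect that budget rather than the estimator's asymptotic behavior.
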