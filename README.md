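# tojpsych

Analysis and simulation tools for multisensory **temporal order judgment
(TOJ)** studies in clinical populations.

In a TOJ task, two stimuli from different modalities (audio–tactile,
audio–visual, visuo–tactile) are presented with a stimulus onset asynchrony
(SOA) and the observer reports which came first. Two quantities summarize
performance: the **point of subjective equality** (PSE, the SOA at which
both orders are reported equally often — a bias/accuracy index) and the
**just noticeable difference** (JND — a precision index; larger JND =
coarser temporal resolution). Reduced temporal precision has been linked to
positive psychotic symptomatology across diagnoses, making JND a candidate
transdiagnostic marker. This package is for psychophysicists and clinical
researchers who want that entire analysis chain — from adaptive trial
placement to symptom regression — as tested, reusable, seedable code, with
a synthetic-cohort generator so every stage can be exercised and validated
without any participant data.

## What it implements

- **QUEST adaptive staircase** (`quest_init`, `quest_next_soa`,
  `quest_update`, `simulate_toj_session`): a discretized Bayesian posterior
  over the observer's temporal threshold on [0, 800] ms, updated trial by
  trial through a Weibull response kernel, with mean/mode/quantile
  placement rules.
- **Psychometric estimation** (`aggregate_proportions`,
  `fit_cumulative_gaussian`, `compute_jnd`): maximum-likelihood fit of
  P(reference first) = Φ((SOA − μ)/σ) at the trial level; PSE = μ,
  JND = (x.75 − x.25)/2 = σ·Φ⁻¹(0.75) ≈ 0.674·σ. Tukey-fence participant
  exclusion via `iqr_outlier_filter`.
- **Group inference** (`permutation_mixed_anova`, `permutation_ttest`,
  `jzs_ttest_bf`, `linear_model_bf`, `generalized_eta_squared`):
  split-plot ANOVA (between: group; within: condition; centered age
  covariate) with Freedman–Lane permutation p-values, Welch permutation
  post-hocs with Bonferroni correction, Jeffreys–Zellner–Siow t Bayes
  factors, and Zellner–Siow mixture-of-g model Bayes factors with a
  participant nuisance block.
- **Symptom models** (`kendall_tau_b`, `clinical_screen`,
  `medication_screen`, `nb_glm_fit`, `nagelkerke_r2`): tie-corrected
  Kendall τ-b screening of mean JND against clinical scales (PANSS
  positive/negative, YMRS, HAM-D) and medication equivalents, and the
  headline negative-binomial GLM `PANSS positive ~ 1 + JND` (log link,
  NB2) with Wald z and Nagelkerke pseudo-R².
- **Synthetic cohorts** (`cohort_config`, `generate_cohort`,
  `simulate_study`): three groups (HC/BD/SZ) with demographic and clinical
  profiles, cumulative-Gaussian observers with group-dependent precision,
  QUEST-driven sessions with skips, and PANSS-positive scores coupled to
  true JND through the same NB model the analysis estimates.
- **Pipeline** (`run_pipeline`): one seeded call from
  `trials.csv`/`participants.csv` (or an in-process synthetic study) to a
  `stats_report.json`; a thin CLI lives at `inst/cli/tojpsych-cli.R`
  (subcommands `simulate`, `fit`, `stats`, `glm`, `all`).

## Worked example

```r
library(tojpsych)

cfg <- cohort_config(n_per_group = c(HC = 12, BD = 12, SZ = 12), rng_seed = 11)
pc  <- pipeline_config(synth = cfg, seed = 101, n_perm = 1999, n_mc_bf = 4000)
report <- run_pipeline(pc)

report$anova_jnd[, c("effect", "df_num", "df_den", "F", "p_perm", "ges")]
#>                effect df_num df_den      F p_perm    ges
#> 1               Group      2     27 20.207 0.0005 0.4986
#> 2                 Age      1     27  1.036 0.3200 0.0249
#> 3           Group:Age      2     27  0.810 0.4410 0.0383
#> 4           Condition      2     54  1.083 0.3670 0.0133
#> 5       Condition:Age      2     54  1.070 0.3470 0.0131
#> 6     Group:Condition      4     54  0.758 0.5335 0.0185
#> 7 Group:Condition:Age      4     54  3.836 0.0350 0.0871

report$posthoc_jnd
#>    pair      t p_perm     bf10 bf_prior_r p_bonferroni
#> 1 HC-BD  -4.08 0.0005 6.90e+01      0.707       0.0015
#> 2 HC-SZ -10.32 0.0005 8.28e+06      0.707       0.0015
#> 3 BD-SZ  -2.12 0.0535 1.62e+00      0.707       0.1605

report$glm_panss_pos$beta1
#> [1] 0.002509276
```

Reading this run: precision (JND) differs strongly by group (permutation
p = 0.0005 is the smallest value attainable at 1999 permutations;
generalized η² ≈ 0.50), both patient groups are less precise than controls
(negative t, decisive Bayes factors) while not differing reliably from each
other, and condition and age contribute little — the simulated cohort
carries a modality-independent precision deficit, and the analysis
recovers it. The fitted NB slope (0.0025 per ms of mean JND, true value
0.002) says each additional 100 ms of JND multiplies the expected
PANSS-positive total by about exp(0.25) ≈ 1.28.

## Vignette

`vignettes/toj-analysis-methods.Rmd` documents the models, the estimation
and permutation machinery, the synthetic-cohort design choices (and what
they do and do not emulate), numerical tolerances, and known limitations.
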