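---
title: "Methods: profiling multiple acute ischemic lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling multiple acute ischemic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model overview

`malprofiler` analyses patient-level stroke cohorts in which each subject
carries acute lesion counts over nine vascular supply territories (left and
right ACA, MCA, PCA and cerebellum, plus the midline brainstem), total DWI
lesion volume, WMH burden, NIHSS, mRS and clinical covariates. The package
has four analysis layers and a synthetic-data layer:

1. **Constellation classification.** A patient has *multiple acute lesions*
   (MAL) whenever the total lesion count exceeds one — lesions need not span
   territories. Categories encode the multiset of per-territory statuses
   ("single" = exactly one lesion in that territory, "multiple" = two or
   more). Derived flags: bilaterality (assessed over lateralized territories
   only; the brainstem is midline and never contributes), combined supra- and
   infratentorial involvement, and combined anterior/posterior circulation
   involvement (ACA/MCA are anterior; PCA, cerebellum and brainstem
   posterior). These two latter flags are logically independent: a PCA +
   cerebellar constellation crosses the tentorium while staying posterior.
2. **Territory tabulation.** Per-territory counts of single- versus
   multiple-lesion involvement are *territory-local*: a patient with one
   lesion in each of two territories is "single" in both rows. This choice is
   forced by consistency — column totals of such tables exceed the number of
   globally single-lesion patients, which a patient-global rule could not
   produce. Percentages are rounded half-up to one decimal, the convention of
   clinical tables; rows with no involved patients report `NA` rather than a
   0/0 artifact.
3. **Group-comparison battery.** Continuous variables use two-sample t-tests
   (Welch by default; a pooled-variance option exists because the classical
   form is common in clinical reporting), binary variables use Fisher's exact
   test, and multi-level variables (e.g. CCS etiology) are expanded into
   one-vs-rest tables with one test per level. Raw p-values are adjusted
   jointly across the whole battery by the Benjamini–Hochberg step-up
   procedure — the standard default where a report says only
   "FDR-corrected" — and significance is declared at adjusted p < 0.05. Each
   variable is analysed on its complete cases with the analysed group sizes
   reported, since clinical variables differ in availability. If a continuous
   variable is constant in *both* groups the battery reports p = 1 with a
   warning instead of aborting: a degenerate column should surface as a
   warning in a report, not kill a pipeline run.
4. **Hierarchical interaction models.** Stroke severity is modelled as

   $$\mathrm{NIHSS}_i \sim N(\alpha_{g(i)} + \beta_{g(i)} \log V_i,\ \sigma^2),$$

   and unfavorable functional outcome as
   $\Pr(\mathrm{mRS}_i > 2) = \mathrm{logit}^{-1}(\alpha_{g(i)} + \beta_{g(i)} \log V_i)$,
   where $V_i$ is total DWI lesion volume in ml and $g(i) \in$
   {single, multiple}. Both group intercepts and slopes are drawn from shared
   hyperpriors, so the two slope estimates live in one model and their
   posterior difference (single − multiple) is available draw-wise. The
   contrast is called **substantial** exactly when the 90% highest posterior
   density interval (HPDI) of the difference excludes zero — a binary
   decision rule, deliberately not a Bayes factor. Gaussian NIHSS on the
   integer 0–42 scale is an approximation (no truncation in the likelihood);
   it is adequate away from the scale's floor and ceiling, which is also why
   the simulation studies below use settings that keep outcomes off the
   bounds.

## Priors, sampler, diagnostics

Published analyses of this design rarely pin priors; we use weakly
informative defaults, all config-exposed in `hier_model_spec()`:
hyperprior locations $\mu_\alpha, \mu_\beta \sim N(0, 10^2)$, hyperprior
scales half-Normal(2.5), residual $\sigma \sim$ half-Normal(10) with a
numerical floor of 0.001 that keeps the precision finite for degenerate
(constant-outcome) inputs. With only two groups the hierarchical scale is
weakly identified; the practical effect is mild partial pooling that shrinks
a spurious slope difference toward zero — which is precisely what makes the
"substantial" verdict conservative under equal true slopes (observed in the
test suite: equal planted slopes yield a difference HPDI containing zero in
~100% of replicates, versus the 90% a non-hierarchical interval would give).

Sampling uses JAGS: defaults 4 chains × 1,000 retained draws after 1,000
adaptation iterations per chain; replicate simulation studies in the test
suite use 2 × 1,000 after 500 to keep the whole study inside a few minutes.
Convergence is summarized by the maximum split potential-scale-reduction
factor; fits exceeding 1.01 are flagged `usable = FALSE` but still returned,
never silently discarded. Divergent-transition counts are reported as `NA`:
they are a Hamiltonian-Monte-Carlo concept without an analogue in the
Gibbs/slice samplers used here. Chain RNGs are seeded deterministically from
the spec seed, so identical spec + seed reproduce identical summaries.

Volumes enter as natural logs; a floor of 0.01 ml (config `log_epsilon`)
guards zero volumes that only arise in synthetic data.

## HPDI definition

`hpdi(draws, mass)` returns the shortest contiguous window of the sorted
draws containing at least `ceiling(mass * n)` draws, ties broken in favour
of the lowest window. This makes the estimator fully deterministic given
draws (important for reproducibility tests) and exactly matched by a
brute-force all-windows search, which the test suite runs on up to 1,000
draws. Width is non-increasing in decreasing mass, and for unimodal samples
the interval brackets the median.

## Stratification protocol

The anterior stratum contains patients whose lesions lie exclusively in
ACA/MCA territories, the posterior stratum those exclusively in
PCA/cerebellum/brainstem. Patients spanning both circulations (~2% under the
default generator) are assigned to neither stratum: any single-stratum
placement would misattribute part of their lesion volume. Lacunar-stroke
patients (single subcortical supratentorial lesion < 1.5 cm) are excluded
from the anterior stratum by default because the lacunar definition
precludes multiple lesions, which would otherwise deplete only one arm of
the comparison; the exclusion can be overridden, and other strata keep
lacunar patients. Fits refuse to run with fewer than 10 patients per group —
below that, slope posteriors are prior-dominated and a verdict would be
noise; the pipeline reports the refusal as a diagnostic line.

## What the synthetic generator emulates

`generator_config()` defaults encode the cohort structure the analysis
expects:

* **Constellation shares**: 49.7% single lesion, 37.4% multiple within one
  territory, and the remaining ~12.9% spread over multi-territory patterns
  (3.2% two singles, 4.1% single + multiple, the rest split between
  double-multiple and three-territory patterns — the published material does
  not resolve these further, so the split is a configurable choice).
  Territory draws are weighted by the observed per-territory patient masses
  (MCA-dominant) and, for multi-territory patients, sampled without
  replacement independently of status — the joint distribution of territory
  combinations is not published, so independence is an explicit assumption.
* **Volumes**: log-normal per group with location fixed at the log of the
  published group median (1.7 ml single / 7.7 ml multiple for DWI; 6.1 / 5.3
  ml for WMH) and scale solved numerically from the published IQR (11.2 /
  30.4 and 14.4 / 11.3 ml). `solve_lognormal_scale()` gives σ ≈ 2.83 / 2.12
  for the DWI groups; the solver's residual IQR error is below 1e-6 ml.
* **Outcomes**: NIHSS is `round(α_g + β_g log V + ε)` clipped to 0–42 with
  circulation-stratum-specific slopes echoing the published posterior means
  (anterior ≈ 1.56 in both groups; posterior 0.21 single vs 0.39 multiple;
  mixed-circulation patients 1.15 / 1.21). Intercepts are not published; the
  defaults are derived so that each group's mean NIHSS matches the published
  4.6 / 6.3 given the group's median log volume, with residual sd 4.0
  (published group SDs of 4.8/6.3 include the volume effect, so the residual
  sd must sit below them). mRS > 2 is drawn from a logistic model with
  default α = −1.2, β = 0.35 in both groups, reflecting the near-zero
  published group difference for functional outcome; the full 0–6 mRS value
  is then sampled within the favorable/unfavorable range purely for file
  realism — analyses only use the dichotomy.
* **Covariates and missingness**: age ~ N(63.4, 14.8²) truncated to 18–100,
  39% women, per-group comorbidity and CCS etiology prevalences as published;
  covariates are sampled independently given group (their joint correlation
  structure is not published). Missingness is completely at random, with
  volume + NIHSS jointly observed in ~41% and mRS in ~30% of patients,
  reproducing the published analysis-subset sizes proportionally.
* **Lacunar flagging**: among eligible patients (single lesion, one
  supratentorial territory, volume < 1.77 ml — the volume of a 1.5 cm
  sphere, a proxy for the diameter criterion) a configurable fraction
  (default 0.149, the small-artery-occlusion share) is flagged.

What the generator does **not** emulate: spatial lesion geometry, per-lesion
volume decomposition (all models use total volume), correlated covariates,
informative missingness, site effects of a multi-center study, and the
empirical single-lesion excess in the brainstem. Passing simulation tests
therefore demonstrates that the statistical machinery recovers what it
assumes — not that real cohorts satisfy those assumptions.

## Simulation-study design choices

Replicate studies (20 seeded replicates each) use cohorts of ~500 patients
per lesion group (≈1,000 for logistic fits, whose slope estimator is
noisier) and a volume model with log-scale sd 1.2 and intercepts placed so
NIHSS stays off the 0 and 42 bounds: with the heavy published dispersion
(sd ≈ 2.8 on the log scale) the floor-clipping alone attenuates slopes by
more than the recovery tolerance, which would test the clipping artifact
rather than the fitter. Under these settings the observed behavior is:
slope bias ≲ 0.02, 90% HPDI coverage within its binomial band, equal planted
slopes yield no "substantial" verdict, and a planted 0.2 vs 0.4 contrast is
flagged in ≥ 90% of replicates. Generator calibration is verified on
20,000-patient groups, averaging the sample median over five replicate
cohorts because a single sample median of the heavy-tailed multiple-lesion
volume distribution carries an SE of ~0.15 ml.

## Numerical conventions and edge cases

* Percentages print half-up at one decimal (`floor(x·10 + 0.5)/10`); note
  that a few published percentages differ from their own printed counts at
  the last digit under any deterministic rounding rule — this package always
  reports the value computed from the counts.
* Zero-lesion records are invalid (the analysis cohort is defined by a
  discernible acute infarct) and rejected with the patient named.
* Fisher's exact test uses the standard two-sided definition (sum of
  hypergeometric probabilities ≤ the observed table's); degenerate tables
  with a zero margin give p = 1.
* BH adjustment is *not* idempotent (re-adjusting adjusted values inflates
  them); the meaningful invariants — agreement with the step-up formula,
  monotonicity against raw p-values, rank preservation, permutation
  equivariance — are the tested ones.
* All randomness flows through explicit seeds; `generate_cohort()` restores
  the caller's RNG state.

## Known limitations

* The Gaussian NIHSS likelihood ignores the bounded integer scale; severe
  floor effects would bias slopes (mitigated but not removed by design in
  simulations; real cohorts with many NIHSS = 0 patients deserve a truncated
  or ordinal likelihood).
* The two-level hierarchy cannot estimate its scale hyperparameters sharply;
  inferences about the *difference* are robust, inferences about the
  hyperparameters themselves are not meaningful.
* Watershed/border-zone lesions are not representable: the input format
  forces each lesion into one territory.
* The mRS dichotomy at > 2 discards ordinal information by design.
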