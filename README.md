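# malprofiler

Profiling of **multiple acute ischemic lesions (MAL)** in stroke cohorts.

A substantial fraction of acute ischemic stroke patients present with more
than one acute lesion on diffusion-weighted imaging (DWI) — within one
vascular territory or across several. This package provides, for
biostatisticians and stroke researchers working with structured
radiological reports, the complete analysis layer for such cohorts:

* **Lesion-constellation classification** over nine vascular supply
  territories (ACA, MCA, PCA left/right, cerebellum left/right,
  brainstem): single vs. multiple lesions, number of involved
  territories, bilaterality, supra-/infratentorial and
  anterior/posterior-circulation involvement, and cohort-level frequency
  tables.
* **A clinical group-comparison battery** (single- vs. multiple-lesion
  patients): two-sample t-tests for continuous variables, Fisher's exact
  tests for binary and one-vs-rest categorical variables, with
  Benjamini–Hochberg FDR correction applied jointly across the battery.
* **Bayesian hierarchical interaction models**: stroke severity
  (NIHSS) and unfavorable functional outcome (mRS > 2) are regressed on
  log total DWI lesion volume with lesion-group-specific intercepts and
  slopes drawn from shared hyperpriors,

  NIHSS_i ~ N(α_g(i) + β_g(i) · log V_i, σ²),   logit P(mRS_i > 2) = α_g(i) + β_g(i) · log V_i,

  g ∈ {single, multiple}. The group slopes are compared through the
  draw-wise posterior **difference distribution** (single − multiple);
  the contrast is called *substantial* when the 90% highest posterior
  density interval (HPDI) of the difference excludes zero. Circulation
  strata (anterior/posterior) are supported, with protocol-conform
  exclusion of lacunar strokes from the anterior stratum.
* **A calibrated synthetic cohort generator** (constellation shares,
  MCA-dominant territory weights, log-normal volume models solved from
  median/IQR targets, outcome models with configurable group slopes,
  covariates and missingness) plus exact-count fixture planting, and an
  **end-to-end pipeline** with manifests and deterministic seeding.

MCMC is performed with JAGS via `rjags`.

## Worked example

```r
library(malprofiler)

cfg      <- generator_config(n_patients = 2466)
cohort   <- generate_cohort(cfg, seed = 7)
labelled <- classify_cohort(cohort)

constellation_frequencies(labelled)
#> Lesion constellations (2466 patients)
#>                                     category    n share_pct
#>                      single-in-one-territory 1269      51.5
#>                    multiple-in-one-territory  876      35.5
#>             multiple+single-in-2-territories  108       4.4
#>               single+single-in-2-territories   71       2.9
#>           multiple+multiple-in-2-territories   65       2.6
#>  ...
#> Marginal flags:
#>             flag    n share_pct
#>              mal 1197      48.5
#>        bilateral  191       7.7
#>  supra_and_infra  157       6.4
#>     ant_and_post  223       9.0
#>  multi_territory  321      13.0
```

About half of the simulated patients carry multiple acute lesions, most of
them within a single territory — the constellation structure the generator
is calibrated to. The comparison battery contrasts the two groups variable
by variable and adjusts the whole battery for multiple testing:

```r
t1 <- compare_groups(labelled)
t1[t1$variable %in% c("af", "dwi_vol_ml", "nihss"),
   c("variable", "summary_single", "summary_multiple", "p_raw", "p_fdr", "significant")]
#>    variable summary_single summary_multiple        p_raw        p_fdr significant
#>          af          11.3%            16.7% 1.514106e-04 6.056422e-04        TRUE
#>  dwi_vol_ml      1.9 (9.9)       7.2 (33.1) 4.906153e-01 5.233230e-01       FALSE
#>       nihss      5.2 (4.6)        6.6 (4.5) 9.304220e-07 4.962251e-06        TRUE
```

Multiple-lesion patients show a higher atrial-fibrillation prevalence and
higher NIHSS after FDR correction (both planted in the generator's
defaults); the volume t-test is insensitive here because the heavy-tailed
volumes are summarized by medians but compared on the raw scale. The
hierarchical severity model estimates the volume–severity slope per group
and their posterior difference:

```r
fit <- fit_hier_linear(stratify_cohort(labelled, "all"),
                       hier_model_spec("linear", seed = 7))
fit
#> Hierarchical linear model (n single = 547, multiple = 510)
#>   slope, single lesions:   mean 0.984, 90% HPDI [0.891, 1.087] (4000 draws)
#>   slope, multiple lesions: mean 1.124, 90% HPDI [0.993, 1.240] (4000 draws)
#>   difference (single - multiple): mean -0.140, 90% HPDI [-0.287, 0.017] (4000 draws)
#>   substantial (HPDI excludes 0): FALSE
#>   max Rhat: 1.004; usable: TRUE
```

Each additional log-ml of lesion volume adds about one NIHSS point in both
groups; the difference's 90% HPDI includes zero, so the interaction is not
substantial in this stratum. `run_pipeline()` chains all stages
(simulate → classify → tabulate → compare → fit → report) into one seeded,
manifest-tracked run; `inst/cli/mal_profiler.R` exposes the same stages as
shell subcommands.

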