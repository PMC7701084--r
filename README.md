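# ttvload

Statistical toolkit for longitudinal Torque teno virus (TTV) plasma-load
monitoring in kidney-transplant cohorts.

TTV is a ubiquitous, non-pathogenic anellovirus whose plasma DNA load tracks
the immune competence of its host: the stronger the immunosuppression, the
higher the load. That makes serial TTV quantification a candidate biomarker
for the *net state of immunosuppression* after transplantation — something
neither drug doses nor trough levels measure directly. This package
implements the statistical machinery for a 12-month monthly monitoring
design in a paediatric kidney-transplant cohort, and a synthetic-cohort
generator that emulates the design so the whole pipeline is testable without
patient data.

## What it computes

For a cohort of patients with monthly visits (TTV load, drug doses, trough
levels, eGFR, co-virus loads, binary event flags):

1. **Left-censored log10 transform.** Loads are reported in
   log10 copies/ml with reportable range [2, 10]; raw values of 0 encode
   samples below the 2 log10 detection limit and are set to 1 before
   transformation, so undetectable maps to log10(1) = 0.

2. **Patient-level associations** (`run_association_scan`). For each fixed
   covariate, the per-patient *mean* log10 load over the study year is
   tested by one-way ANOVA (categorical covariates) or simple linear
   regression (continuous covariates).

3. **Repeated-measures correlation** (`mean_correlation_permutation_test`).
   For each monthly metric covariate *z*, Spearman's rank correlation
   ρᵢ = cor(rank TTVᵢₜ, rank zᵢₜ) is computed per patient, and the cohort
   statistic T = mean(ρᵢ) is tested with a within-patient permutation test:
   each iteration independently permutes every patient's covariate series in
   time (TTV held fixed) and recomputes T; the two-sided p-value is
   (#{|T*| ≥ |T|} + 1)/(B + 1) with B = 10,000 iterations by default.

4. **Random-intercept logistic regression** (`fit_random_intercept_logit`).
   For a binary monthly outcome y (infection, infection next month, fever,
   non-adherence):

       logit P(yᵢₜ = 1 | uᵢ) = α + β·TTVᵢₜ + uᵢ,   uᵢ ~ N(0, σᵤ²)

   fitted from scratch by maximum marginal likelihood with adaptive
   Gauss–Hermite quadrature; Wald CI exp(β ± 1.96·SE) on the odds-ratio
   scale. The "next month" model pairs the TTV load at month m with the
   infection flag at month m + 1 (strictly adjacent months).

5. **Synthetic cohorts** (`generate_cohort`). Latent load
   Lᵢₜ = baseline + regimen effect + slope·(post-transplant years) + bᵢ + εᵢₜ
   with AR(1) monthly noise, detection-limit censoring, a calibrated
   within-patient dose–load rank correlation, and Bernoulli event flags with
   patient-level intercepts — every injected effect is recoverable by the
   matching analysis stage.

## Worked example

The `analysis/` directory is a numbered workflow over the package:

```sh
Rscript analysis/01_simulate.R       # build the cohort under results/cohort/
Rscript analysis/02_associations.R   # patient-level tests
Rscript analysis/03_correlations.R   # permutation-tested correlations
Rscript analysis/04_event_models.R   # mixed logistic event models
```

`01_simulate.R` generates 45 patients with ~12 monthly visits and prints

```
cohort: 45 patients, 511 monthly samples
TTV DNA detectable in 504/511 samples (98.6%)
median detectable load 5.3 log10 copies/ml (IQR 4.2-6.6)
```

`02_associations.R` finds, on this cohort, exactly the two covariates the
generator couples to the load — the regimen class (mTOR-inhibitor patients
run ≈2 log10 lower) and the post-transplant time (loads decline with years
since transplant):

```
cni_vs_mtori [anova]: stat = 11.51, p = 0.001496, n = 45
post_transplant_time [linear_regression]: stat = -2.567, p = 0.0138, n = 45
```

`03_correlations.R` detects the injected within-patient prednisolone-dose
coupling and nothing else:

```
prednisolone_dose: mean rho = 0.143 over 45 patients, p = 0.002 (B = 10000)
tacrolimus_trough: mean rho = -0.030 over 38 patients, p = 0.5605 (B = 10000)
egfr: mean rho = -0.007 over 45 patients, p = 0.879 (B = 10000)
```

`04_event_models.R` fits the four event models; with the default null slope
the odds ratios per log10 TTV sit near 1:

```
infection: OR = 0.999 [0.849, 1.176], p = 0.991, sigma_u = 0.729 (n = 511 obs, 45 patients)
infection_next_month: OR = 0.965 [0.810, 1.149], p = 0.688, sigma_u = 0.725 (n = 439 obs, 45 patients)
```

Each step also writes its table under `results/tables/`
(`table2_associations.csv`, `table3_correlations.csv`,
`table4_mixed_logit.csv`). `run_pipeline()` chains all stages and adds a
JSON manifest; identical cohort, seed and configuration give byte-identical
bundles.

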