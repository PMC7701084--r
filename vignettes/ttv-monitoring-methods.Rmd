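---
title: "Methods: longitudinal TTV load analysis and its synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal TTV load analysis and its synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttvload)
```

## The monitoring design

Torque teno virus (TTV) is a near-universal, apathogenic passenger virus
whose plasma DNA load rises when host immunity is suppressed. In transplant
medicine this suggests a functional read-out of the *net state of
immunosuppression*: drug doses describe what was prescribed and trough
levels what was absorbed, but neither measures how suppressed the immune
system actually is. The design this package supports is a one-year
monitoring study: each patient contributes roughly monthly visits at which
TTV load, immunosuppressant doses and trough levels, eGFR, co-virus loads
(EBV, CMV, BKV) and binary clinical events (microbial infection, febrile
infection, suspected non-adherence) are recorded.

Three questions drive the three analysis stages:

* Do *patient-level* characteristics (regimen, demographics, transplant
  history) shift a patient's average load?
* Do *monthly* covariates co-move with the load within a patient?
* Does the load predict *events*, at the same visit or one month ahead?

## Data model and the censored transform

Loads are measured on a quantitative PCR assay with reportable range 2–10
log10 copies/ml and detection limit 2 log10 copies/ml. A raw value of 0
encodes "below detection"; raw values in (0, 1) cannot occur. Before
analysis all viral counts are log10-transformed with zeros set to 1, so an
undetectable sample enters every analysis as 0 and the transformed scale is
{0} ∪ [2, 10]. This convention is deliberate: it preserves undetectable
samples as the lowest rank rather than discarding them, at the cost of a
7-unit gap below the quantifiable range. Per-patient means therefore
*include* undetectable visits as 0 — the transform rule implies this
mechanically, and dropping them would bias the mean of exactly the patients
whose suppression is weakest. Months with no measurement are absent rows and
contribute nothing (complete-case per time point; no imputation).

The schema separates "not measured" (empty cell) from "measured as zero"
(raw 0): dose and trough columns of drugs a patient is not on are missing,
never zero-filled, which is what restricts drug-specific correlations to the
patients actually taking the drug.

eGFR, where it must be computed from primary measurements, uses the original
Schwartz formula k × height(cm) / creatinine(mg/dl), with the conventional
constants (0.45 infants < 1 y, 0.70 adolescent males, 0.55 otherwise) unless
the caller supplies k.

## Patient-level associations

For each fixed covariate, the response is the patient's mean log10 load over
the year. Categorical and binary covariates use classical one-way ANOVA
(for two groups this is exactly the pooled-variance t test, F = t²);
continuous covariates use ordinary least squares with the t test of the
slope. Two conventions worth stating:

* When every group mean is equal (no between-group variance) the F statistic
  is reported as 0 with p = 1, which also covers the degenerate case where
  the within-group variance is 0 and F would otherwise be 0/0.
* The HLA mismatch count defaults to the regression path (treated as
  continuous); a switch runs it through ANOVA instead, since a count with
  range 0–6 sits on the boundary between the two families.

No covariate adjustment and no multiple-testing correction are applied. The
design is exploratory and the p-values are descriptive; correcting them is a
decision for the study protocol, not the toolkit.

## Repeated-measures correlation with a within-patient permutation test

The quantity of interest is the *within-patient* association between the
monthly load and a monthly covariate. Pooling all visits would confound
within- and between-patient variation, and a parametric repeated-measures
model would impose linearity. Instead, per patient i, Spearman's ρᵢ is
computed across that patient's months (Pearson correlation of midranks;
pairwise deletion of incomplete pairs), and the cohort statistic is the
unweighted mean T = mean(ρᵢ).

Patients contribute only with at least `min_pairs` complete pairs (default
3, the smallest series with a nondegenerate rank correlation) and a defined
ρᵢ (a constant series has none). Excluded patients are excluded from both
the observed and the permuted statistic, so both are computed on the same
set.

Significance comes from a permutation test under the minimal exchangeability
assumption that targets this statistic: within each patient, the *time
order* of the covariate series is permuted independently and uniformly, the
TTV series is held fixed, and T is recomputed; B = 10,000 iterations by
default. The two-sided p-value uses the add-one correction
p = (#{|T*| ≥ |T|} + 1)/(B + 1), which makes the test valid at any finite B
and floors p at 1/(B + 1). Magnitude comparisons use a 10⁻¹² tolerance so
that permutations reproducing the observed ranking count as ties rather than
falling to floating-point noise.

Two genuinely open choices are resolved as follows and flagged here:
two-sided testing (the monitoring question is directionless a priori), and
permutation *within* patients rather than across the pooled series (pooled
permutation would destroy the patient structure the statistic deliberately
respects). Holding TTV fixed preserves its autocorrelation; permuting the
covariate does assume its time points are exchangeable within a patient, so
for covariates with strong trends the test can be anticonservative — the
type-I-error simulations in the test suite quantify this under the
generator's default AR(1) strength of 0.3 and find the level within binomial
error of nominal.

The permutation loop is the package's only compiled code: midranks are
computed once in R, centred and normalised, and the C++ kernel only permutes
and takes dot products (a Spearman ρ of two series *is* the dot product of
their normalised midrank vectors, and permuting a series permutes its
midranks). The kernel draws from R's RNG, so a seed makes the whole result —
per-patient ρ, mean, p — bit-reproducible.

## Random-intercept logistic regression by Gauss–Hermite quadrature

Event models share one form: logit P(yᵢₜ = 1 | uᵢ) = α + β·xᵢₜ + uᵢ with
uᵢ ~ N(0, σᵤ²), where x is the log10 load. Four outcomes are fitted
separately: infection and suspected non-adherence at the same visit, febrile
infection as a subgroup outcome, and microbial infection at the *following*
month, with predictor–outcome pairs built only from strictly adjacent
calendar months (a gap breaks the chain; no tolerance window, the strictest
reading of "one month before onset").

The marginal likelihood integrates each patient's random intercept out of
the Bernoulli product. The integral is evaluated by Gauss–Hermite
quadrature, by default 21 nodes in the *adaptive* form: a damped Newton
iteration finds each patient's posterior mode and curvature, and the nodes
are centred and scaled there. Adaptivity matters in practice — outcomes that
are strongly patient-clustered (non-adherence: a quarter of patients flag
repeatedly, the rest never) drive σᵤ to 5–7, where static nodes placed at
±σᵤ√2·z mis-sample the integrand; the test suite checks both rules against
brute-force trapezoid integration of the same integrand (20,001 grid points
over ±8σᵤ) to 10⁻⁶ per patient.

Optimization is quasi-Newton (BFGS) over (α, β, log σᵤ), started from the
plain logistic fit and σᵤ = 0.5, with relative tolerance 10⁻¹² and at most
500 iterations. Numerical choices at the boundary:

* σᵤ is parameterized on the log scale, so the boundary σᵤ = 0 is never hit
  directly. After optimization the boundary is *profiled*: if the plain
  logistic log-likelihood is within 10⁻⁶ of the optimum, or the estimate
  collapses below 10⁻⁴, the model is refit as plain logistic with σᵤ
  reported as 0.
* With one observation per patient the random intercept is unidentifiable
  (the likelihood has a flat ridge in (β, σᵤ)); this case is detected up
  front and reported as the plain logistic fit with σᵤ = 0.
* Quasi-complete separation is detected at the starting fit (unconverged
  IRLS or |coefficient| > 15) and raised as a diagnostic error rather than
  returning a spurious estimate; an outcome observed in a single class is
  likewise an error, and the four-model driver reports such outcomes as
  not-fitted while the others proceed.

Standard errors come from the inverse of the observed information (numerical
Hessian at the optimum); the 95% interval is Wald on the log-odds scale,
exp(β ± 1.96·SE) — symmetric in log-odds, matching the usual "OR 2.5% / OR
97.5%" presentation. Profile-likelihood intervals are a possible refinement
the package does not implement; at the cluster counts targeted here Wald and
profile intervals differ little for β (they can differ for σᵤ, which is
reported without an interval).

The implementation is validated three ways: reduction to an independent
Newton–Raphson plain-logistic oracle at the boundary, agreement of the
quadrature likelihood with brute-force integration, and agreement of full
fits with `lme4::glmer` at matched node counts (cross-check only; `lme4` is
never used in the computation path).

## The synthetic cohort generator

The generator emulates the *statistical structure* the analyses assume — not
TTV biology. Defaults describe the study conditions: 45 patients, 12 monthly
slots, ~6% of slots missing (so ≈509 of 540 visits), baseline mean 5.8
log10, detection floor 2 and ceiling 10, an mTORi regimen shift of −2 log10,
a post-transplant-time slope of −0.1 log10/year, a within-patient
prednisolone-dose rank correlation of 0.224, regimen/anti-proliferative/
disease/donation frequencies matching the cohort's (39/3/3 tacrolimus/
cyclosporin/rapamycin, etc.), a per-visit infection rate of 119/509 with
zero TTV slope (the null the study observed), a febrile fraction of 20/119,
and 24% of patients prone to non-adherence flags.

The latent load is

L = baseline + regimen effect + slope·(post-tx years) + bᵢ + εᵢₜ,

with bᵢ ~ N(0, 1.3²) between patients and εᵢₜ an AR(1) fluctuation with SD
0.9 and lag-1 correlation 0.3. The variance split is an assumption: the
study publishes only the pooled per-sample spread (IQR 4.5–6.7 log10, i.e.
total SD ≈ 1.6), and 1.3/0.9 respects that total while giving patients the
stable individual "set point" TTV kinetics show; monthly biological series
are autocorrelated, hence AR(1), configurable to 0 for i.i.d. tests.
Censoring is applied at observation: raw load is 0 below the floor,
10^min(L, 10) otherwise.

The dose–load coupling shares a latent AR(1) process z between the
prednisolone dose (dose = 5 + 1.2·z, monotone in z) and the load's monthly
fluctuation ε = 0.9·(a·z + √(1−a²)·w). For a bivariate normal pair with
Pearson correlation a, the population Spearman correlation is
(6/π)·asin(a/2), so the loading is set once, analytically, to
a = 2·sin(π·ρ_target/6); left-censoring ties a few percent of load values at
0 and attenuates the realised correlation only slightly at the default
detectable fraction (~95%). Trough levels are generated independent of the
load, mirroring the null finding monitoring studies report for troughs.

Infection flags are Bernoulli with logit α + β·x + uᵢ where x is the
*observed* (censored) log10 load. Using the observed rather than the latent
load is a deliberate choice: the injected slope then lives on exactly the
scale the analysis model sees, so round-trip recovery (generate with β,
refit, compare) is a clean identity check instead of being confounded with
censoring attenuation. α is solved from the configured marginal rate.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: irregular visit calendars (slots are idealized to
calendar months), measurement error in doses and troughs, informative
missingness (slots are missing completely at random), seasonal or outbreak
structure in infections, co-virus dynamics coupled to immunosuppression, and
any nonlinearity in the dose–load relationship. Tests against generated
cohorts validate the *statistics*, not the biology.

## Problem sizes and numerical budgets

The simulation-based checks in the test suite use: 1,000 null cohorts at
45 × 12 with 200 permutations each for the type-I error of the permutation
test; the 2-patient × 3-visit fixture, where all (3!)² = 36 joint
permutations can be enumerated, for exactness; 1,000 random tied series for
the Spearman midrank oracle; 200 replicates at 200 patients × 12 visits for
infection-slope recovery and interval coverage; and a 2,000-patient cohort
for the regimen-gap round trip. These sizes were chosen so each check's
Monte-Carlo error is small relative to the effect it measures while the
whole suite stays a desk-scale computation.

One recovery result deserves honesty: at 200 patients the maximum-likelihood
slope estimate carries the well-known O(1/n) attenuation bias of logistic
mixed models (≈ −0.005 at β = 0.5 here, indistinguishable from `glmer`'s),
which is the same order as the standard error of a 200-replicate mean. The
recovery check is kept at the strict "bias below the SE of the mean"
reading and documents this: the estimator is exactly ML, and ML is what it
is at finite n.

## Known limitations

* The permutation test assumes within-patient exchangeability of the
  covariate under the null; strongly trending covariates can inflate the
  type-I error (quantified only at AR(1) = 0.3).
* Wald intervals and p-values for the mixed models rely on asymptotics in
  the number of patients; with very few patients (e.g. the 2–5 patients on
  minority regimens) they are unreliable, which is why the drug-specific
  correlation rows carry small `n_patients` and should be read accordingly.
* One fixed effect per event model, by design; confounding by indication
  (sicker patients get more drug *and* more infections) is out of scope.
* The generator's variance decomposition and event-clustering parameters are
  assumptions documented above, not published quantities.
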