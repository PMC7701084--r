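Package: ttvload
Title: Longitudinal Torque Teno Virus Load Analysis for Transplant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for 12-month longitudinal Torque teno virus
    (TTV) plasma-load monitoring in kidney-transplant cohorts. Implements the
    left-censored log10 viral-load transform, per-patient summaries, patient-level
    association tests (one-way ANOVA and simple linear regression of mean log10
    TTV on clinical covariates), a repeated-measures correlation procedure
    (per-patient Spearman rank correlation with a within-patient permutation
    test of the cohort mean), and random-intercept logistic regression of
    binary monthly outcomes on TTV load fitted by maximum marginal likelihood
    with Gauss-Hermite quadrature. A synthetic-cohort generator emulates the
    study's data structure (regimen effects, AR(1) within-patient dynamics,
    detection-limit censoring, sparse binary events) so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
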