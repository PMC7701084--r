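test_that("spearman_rho agrees with rank-then-Pearson on tied data", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)

  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2.1, 2.1, 4.0, 3.5, 6.0, 5.0)
  expect_equal(spearman_rho(x, y),
               cor(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average")),
               tolerance = 1e-14)

  # degenerate cases signal NA, not an error
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))))
  expect_true(is.na(spearman_rho(c(2, 2, 2, 2), c(1, 3, 2, 4))))
  # pairwise deletion of missing values
  expect_equal(spearman_rho(c(1, 2, NA, 4, 3), c(5, 6, 1, 8, 7)), 1)
})

test_that("spearman_rho is invariant to strictly monotone transforms", {
  set.seed(201)
  for (rep in 1:20) {
    x <- sample(1:8, 7, TRUE); y <- rnorm(7)
    r0 <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r0, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3), r0, tolerance = 1e-12)
    expect_equal(spearman_rho(10 * x - 3, log(y - min(y) + 1)), r0,
                 tolerance = 1e-12)
  }
})

test_that("per-patient correlations exclude undefined and ineligible patients", {
  set.seed(202)
  co <- mini_cohort(list(prednisolone_dose = c(3, 4, 5, 6, 6, 6)),
                    n_months = 3)
  # patient B has a constant dose series: undefined rho, excluded
  rho <- per_patient_correlations(co, "prednisolone_dose")
  expect_named(rho, "A")
  expect_true(all(rho >= -1 & rho <= 1))

  # nobody on cyclosporin: no eligible patients at all
  expect_error(per_patient_correlations(co, "cyclosporin_dose"),
               "cyclosporin_dose")

  # min_pairs gate
  co2 <- generate_cohort(generator_config(n_patients = 10, seed = 5))
  rho3 <- per_patient_correlations(co2, "prednisolone_dose", min_pairs = 3)
  rho12 <- per_patient_correlations(co2, "prednisolone_dose", min_pairs = 12)
  expect_lte(length(rho12), length(rho3))

  # drug-specific variables only include patients on the drug
  n_rapa <- sum(co2$patients$cni_or_mtori == "rapamycin")
  if (n_rapa >= 1) {
    rr <- tryCatch(per_patient_correlations(co2, "rapamycin_dose"),
                   error = function(e) numeric(0))
    expect_lte(length(rr), n_rapa)
  }
})

test_that("permutation test is reproducible and respects its p-value floor", {
  co <- generate_cohort(generator_config(n_patients = 15, seed = 8))
  r1 <- mean_correlation_permutation_test(co, "egfr", 500, seed = 99)
  r2 <- mean_correlation_permutation_test(co, "egfr", 500, seed = 99)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 501)
  expect_equal(r1$mean_rho, mean(r1$per_patient_rho))
  expect_equal(r1$n_patients, length(r1$per_patient_rho))
})

test_that("a covariate identical to TTV gives the maximal statistic", {
  co <- generate_cohort(generator_config(n_patients = 10, seed = 9,
                                         visit_missingness = 0))
  co$visits$egfr <- co$visits$ttv_log10 + 1  # perfectly concordant
  r <- mean_correlation_permutation_test(co, "egfr", 1000, seed = 1)
  expect_equal(r$mean_rho, 1, tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)
})

test_that("observed statistic matches spearman_rho patient by patient", {
  co <- generate_cohort(generator_config(n_patients = 12, seed = 10))
  r <- mean_correlation_permutation_test(co, "prednisolone_dose", 10, seed = 1)
  v <- co$visits
  for (pid in names(r$per_patient_rho)) {
    rows <- v$patient_id == pid & !is.na(v$prednisolone_dose) &
      !is.na(v$ttv_log10)
    expect_equal(unname(r$per_patient_rho[pid]),
                 spearman_rho(v$ttv_log10[rows], v$prednisolone_dose[rows]),
                 tolerance = 1e-12)
  }
})

test_that("sampled permutation p agrees with exhaustive enumeration (tiny)", {
  fx <- make_fixture("tiny")
  r <- mean_correlation_permutation_test(fx$cohort, "prednisolone_dose",
                                         10000, seed = 4)
  v <- fx$cohort$visits
  series <- lapply(split(v, v$patient_id), function(d) {
    data.frame(x = d$ttv_log10, y = d$prednisolone_dose)
  })
  null_exact <- enumerate_mean_rho(series)  # all (3!)^2 = 36 joint perms
  expect_length(null_exact, 36L)
  p_exact <- mean(abs(null_exact) >= abs(r$mean_rho) - 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / r$n_permutations)
  expect_lt(abs(r$p_value - p_exact), 3 * mc_se + 2 / r$n_permutations)
})

test_that("the test detects an injected dose-load correlation (power)", {
  set.seed(204)
  seeds <- sample.int(1e6, 60)
  rejections <- 0
  for (s in seeds) {
    co <- generate_cohort(generator_config(dose_corr_target = 0.25, seed = s))
    r <- mean_correlation_permutation_test(co, "prednisolone_dose", 200,
                                           seed = s + 1)
    if (r$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / length(seeds), 0.5)
})
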