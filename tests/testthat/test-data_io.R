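test_that("write then read round-trips a valid cohort", {
  fx <- make_fixture("dose_effect")
  dir <- withr::local_tempdir()
  write_cohort(fx$cohort, dir)
  back <- read_cohort(file.path(dir, "patients.csv"),
                      file.path(dir, "visits.csv"))
  expect_equal(back$patients, fx$cohort$patients)
  expect_equal(back$visits, fx$cohort$visits, tolerance = 1e-12)
})

test_that("validation rejects each schema violation with a named error", {
  fx <- make_fixture("tiny")
  p <- fx$cohort$patients
  v <- fx$cohort$visits[names(fx$cohort$visits) != "ttv_log10"]

  # ttv_log10 in the forbidden gap (0, 2)
  v2 <- v; v2$ttv_raw[1] <- 10^1.5
  expect_error(new_cohort(p, v2), "outside \\{0\\} U \\[2, 10\\]")
  # above the reportable ceiling
  v2 <- v; v2$ttv_raw[1] <- 10^10.5
  expect_error(new_cohort(p, v2), "outside")
  # duplicate visit key
  v2 <- rbind(v, v[1, ])
  expect_error(new_cohort(p, v2), "duplicate \\(patient_id, month_index\\)")
  # duplicate patient key
  expect_error(new_cohort(rbind(p, p[1, ]), v), "duplicate patient_id: T01")
  # orphan visit
  v2 <- v; v2$patient_id[4] <- "GHOST"
  expect_error(new_cohort(p, v2), "unknown patient: GHOST")
  # exclusion rule: under 3 months post-transplant
  p2 <- p; p2$post_transplant_time[1] <- 0.1
  expect_error(new_cohort(p2, v), "post_transplant_time below 0.25")
  # febrile infection implies infection
  v2 <- v; v2$febrile_infection[1] <- TRUE; v2$infection[1] <- FALSE
  expect_error(new_cohort(p, v2), "febrile_infection without infection")
  # drug columns must stay missing off-regimen (never zero-filled)
  v2 <- v; v2$rapamycin_dose[1] <- 0
  expect_error(new_cohort(p, v2), "not on rapamycin")
  v2 <- v; v2$mmf_dose[4] <- 0  # patient T02 takes no anti-proliferative
  expect_error(new_cohort(p, v2), "not on MMF")
})

test_that("raw viral loads of 0 encode below-detection and survive I/O", {
  co <- mini_cohort(list(ttv_raw = c(0, 10^4, 10^5, 0, 10^6, 10^2)))
  expect_equal(co$visits$ttv_log10, c(0, 4, 5, 0, 6, 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "patients.csv"),
                      file.path(dir, "visits.csv"))
  expect_equal(back$visits$ttv_log10, c(0, 4, 5, 0, 6, 2), tolerance = 1e-12)
  # missing values stay missing, not zero
  expect_true(all(is.na(back$visits$cyclosporin_dose)))
})

test_that("result writer emits sorted, repeatable tables and rejects empties", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  expect_error(write_results(list(), dir1), "empty result")

  corr <- structure(list(variable = "prednisolone_dose",
                         per_patient_rho = c(A = 0.2, B = 0.25),
                         mean_rho = 0.224, p_value = 0.0008,
                         n_patients = 2L, n_permutations = 10000L,
                         seed = 7L),
                    class = "ttv_correlation")
  assoc <- structure(list(variable = "gender", family = "anova",
                          statistic = 0.66, effect = c(male = 5.2),
                          p_value = 0.42, n = 45L),
                     class = "ttv_association")
  ml <- structure(list(outcome = "infection", beta = 0.0159,
                       se_beta = 0.076, or_estimate = 1.016,
                       or_lower = 0.876, or_upper = 1.180,
                       p_value = 0.832, sigma_u = 0.8, intercept = -1.2,
                       n_obs = 509L, n_patients = 45L, converged = TRUE),
                  class = "ttv_mixed_logit")

  write_results(list(corr, assoc, ml), dir1)
  write_results(list(corr, assoc, ml), dir2)
  for (f in c("table2_associations.csv", "table3_correlations.csv",
              "table4_mixed_logit.csv")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  tab3 <- read.csv(file.path(dir1, "table3_correlations.csv"))
  expect_equal(tab3$variable, "prednisolone_dose")
  expect_equal(tab3$mean_rho, 0.224)
  expect_equal(tab3$p_value, 0.0008)
})

test_that("random cohorts survive the write-read round trip (property sweep)", {
  for (seed in c(11L, 12L, 13L)) {
    co <- generate_cohort(generator_config(n_patients = 12, seed = seed))
    dir <- withr::local_tempdir()
    write_cohort(co, dir)
    back <- read_cohort(file.path(dir, "patients.csv"),
                        file.path(dir, "visits.csv"))
    expect_equal(back$patients, co$patients, tolerance = 1e-12)
    expect_equal(back$visits, co$visits, tolerance = 1e-12)
  }
})
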