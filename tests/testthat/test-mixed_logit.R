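sim_ri_data <- function(n_pat, n_per, alpha, beta, sigma_u, seed) {
  set.seed(seed)
  pid <- rep(sprintf("P%03d", seq_len(n_pat)), each = n_per)
  x <- round(runif(n_pat * n_per, 2, 9), 2)
  u <- rep(rnorm(n_pat, 0, sigma_u), each = n_per)
  y <- as.integer(runif(n_pat * n_per) < plogis(alpha + beta * x + u))
  data.frame(patient_id = pid, ttv_log10 = x, outcome = y,
             stringsAsFactors = FALSE)
}

test_that("quadrature log-likelihood matches brute-force integration", {
  d <- sim_ri_data(6, 8, -1, 0.3, 1.2, seed = 301)
  for (sg in c(0.4, 1.2)) {
    ll_quad <- ri_logit_loglik(-0.8, 0.25, sg, d$ttv_log10, d$outcome,
                               d$patient_id, quad_spec(21))
    ll_trap <- trapezoid_ri_loglik(-0.8, 0.25, sg, d$ttv_log10, d$outcome,
                                   d$patient_id)
    expect_lt(abs(ll_quad - ll_trap) / 6, 1e-6)  # per-patient agreement
    # adaptive rule agrees with the static one at high node counts
    ll_ad <- ri_logit_loglik(-0.8, 0.25, sg, d$ttv_log10, d$outcome,
                             d$patient_id, quad_spec(21, adaptive = TRUE))
    expect_lt(abs(ll_ad - ll_trap) / 6, 1e-6)
  }
})

test_that("estimates stabilise beyond 15 quadrature nodes", {
  d <- sim_ri_data(30, 10, -1.5, 0.4, 1, seed = 302)
  b15 <- fit_random_intercept_logit(d, quad_spec(15))$beta
  b21 <- fit_random_intercept_logit(d, quad_spec(21))$beta
  b31 <- fit_random_intercept_logit(d, quad_spec(31))$beta
  expect_lt(abs(b21 - b15), 1e-4)
  expect_lt(abs(b31 - b21), 1e-4)
})

test_that("one observation per patient reduces to plain logistic regression", {
  d <- sim_ri_data(80, 1, -1, 0.35, 0, seed = 303)
  fit <- fit_random_intercept_logit(d, quad_spec(21))
  oracle <- newton_logistic(d$ttv_log10, d$outcome)
  expect_equal(fit$sigma_u, 0)
  expect_lt(abs(fit$beta - oracle$beta), 1e-6)
  expect_lt(abs(fit$intercept - oracle$alpha), 1e-6)
  expect_lt(abs(fit$se_beta - oracle$se_beta), 1e-6)
  expect_true(fit$converged)
})

test_that("fit agrees with an adaptive-quadrature mixed-model package", {
  skip_if_not_installed("lme4")
  d <- sim_ri_data(60, 10, -1, 0.4, 1, seed = 304)
  fit <- fit_random_intercept_logit(d, quad_spec(25))
  g <- lme4::glmer(outcome ~ ttv_log10 + (1 | patient_id), data = d,
                   family = binomial(), nAGQ = 25)
  expect_equal(fit$beta, unname(lme4::fixef(g)[2]), tolerance = 1e-3)
  expect_equal(fit$sigma_u,
               sqrt(unname(lme4::VarCorr(g)$patient_id[1])),
               tolerance = 1e-2)
})

test_that("result invariants hold: OR scale, CI symmetry, degenerate inputs", {
  d <- sim_ri_data(40, 8, -1, 0.3, 0.8, seed = 305)
  fit <- fit_random_intercept_logit(d, quad_spec())
  expect_equal(fit$or_estimate, exp(fit$beta))
  expect_lte(fit$or_lower, fit$or_estimate)
  expect_gte(fit$or_upper, fit$or_estimate)
  expect_gte(fit$sigma_u, 0)
  # Wald interval symmetric on the log-odds scale
  expect_equal(log(fit$or_upper) - fit$beta, fit$beta - log(fit$or_lower),
               tolerance = 1e-10)

  d0 <- d; d0$outcome <- 0L
  expect_error(fit_random_intercept_logit(d0, quad_spec()), "single class")
  d1 <- d[d$patient_id == d$patient_id[1], ]
  expect_error(fit_random_intercept_logit(d1, quad_spec()), "2 patients")
})

test_that("quasi-complete separation is reported as a diagnostic error", {
  d <- data.frame(patient_id = rep(c("A", "B", "C", "D"), each = 4),
                  ttv_log10 = rep(c(2, 3, 7, 8), each = 4),
                  outcome = rep(c(0L, 0L, 1L, 1L), each = 4))
  expect_error(fit_random_intercept_logit(d, quad_spec()), "separation")
})

test_that("the four event models run, skipping single-class outcomes", {
  fx <- make_fixture("null")
  co <- fx$cohort
  co$visits$febrile_infection <- FALSE  # degenerate fever outcome
  res <- run_event_models(co, quad_spec())
  expect_named(res, c("infection", "infection_next_month", "fever",
                      "nonadherence"))
  expect_s3_class(res$fever, "ttv_skipped")
  expect_match(res$fever$message, "single class")
  for (nm in c("infection", "infection_next_month", "nonadherence")) {
    expect_s3_class(res[[nm]], "ttv_mixed_logit")
  }
  # lagged model uses strictly adjacent months: fewer rows than same-month
  expect_lt(res$infection_next_month$n_obs, res$infection$n_obs)

  # deterministic: identical fits across runs
  res2 <- run_event_models(co, quad_spec())
  expect_identical(res$infection, res2$infection)
})

test_that("an injected infection slope is recovered on a large cohort", {
  cfg <- generator_config(n_patients = 400, infection_beta = 0.3,
                          infection_sigma_u = 0.8, seed = 306)
  co <- generate_cohort(cfg)
  res <- run_event_models(co, quad_spec())
  fit <- res$infection
  # OR approx exp(0.3) = 1.35, within the fit's own confidence bounds
  expect_gt(fit$or_upper, exp(0.3) * 0.99)
  expect_lt(fit$or_lower, exp(0.3) * 1.01)
  expect_lt(abs(fit$beta - 0.3), 3 * fit$se_beta)
})
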