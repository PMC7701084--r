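#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the statistical structure of a 45-patient paediatric
#' kidney-transplant cohort followed monthly for a year: log10 TTV loads
#' centred near 5.8 with detection-limit censoring at 2 log10 copies/ml,
#' an mTOR-inhibitor regimen effect of about -2 log10, a mild negative
#' post-transplant-time trend, a weak positive within-patient correlation
#' between prednisolone dose and TTV load, a visit-missingness rate giving
#' roughly 509 of 540 slots, and sparse binary infection / fever /
#' non-adherence events.
#'
#' @param n_patients cohort size (default 45).
#' @param n_months monthly slots per patient (default 12).
#' @param visit_missingness probability a slot is unobserved (default 0.06).
#' @param detection_floor,ceiling assay reportable range in log10 copies/ml
#'   (defaults 2 and 10); latent loads below the floor are reported as raw 0.
#' @param baseline_mean cohort-level mean latent log10 load (default 5.8).
#' @param between_patient_sd,within_patient_sd SDs of the patient random
#'   level and the monthly fluctuation, log10 scale (defaults 1.3, 0.9).
#' @param ar1_rho lag-1 autocorrelation of the monthly fluctuation (default
#'   0.3; set 0 for i.i.d. noise).
#' @param mtori_effect additive log10 shift for rapamycin-based regimens
#'   (default -2).
#' @param post_tx_slope log10 change per post-transplant year (default -0.1).
#' @param dose_corr_target population within-patient Spearman correlation
#'   between prednisolone dose and TTV load (default 0.224); induced by a
#'   latent monthly process shared between dose and load, with Pearson
#'   loading 2 sin(pi rho / 6) (the exact Gaussian rank-correlation
#'   inversion).
#' @param infection_beta log-odds of infection per log10 TTV (default 0, the
#'   null the study observed).
#' @param infection_base_rate marginal per-visit infection probability
#'   (default 119/509).
#' @param infection_sigma_u SD of the patient-level infection intercept
#'   (default 0.8).
#' @param febrile_given_infection probability an infection is febrile
#'   (default 20/119).
#' @param nonadherence_patient_fraction fraction of patients ever suspected
#'   non-adherent (default 0.24).
#' @param nonadherence_month_prob monthly flag probability for those patients
#'   (default 0.6).
#' @param regimen_probs,antiprolif_probs,disease_probs,donation_probs named
#'   category distributions (defaults follow the study cohort's frequencies).
#' @param male_prob,dsa_prob Bernoulli rates for gender and DSA positivity.
#' @param age_mean,age_sd,post_tx_mean,post_tx_sd recipient age and
#'   post-transplant time distributions in years.
#' @param seed integer seed; generation is fully reproducible.
#' @return a validated \code{ttv_gen_config} list.
#' @export
generator_config <- function(n_patients = 45,
                             n_months = 12,
                             visit_missingness = 0.06,
                             detection_floor = 2,
                             ceiling = 10,
                             baseline_mean = 5.8,
                             between_patient_sd = 1.3,
                             within_patient_sd = 0.9,
                             ar1_rho = 0.3,
                             mtori_effect = -2.0,
                             post_tx_slope = -0.10,
                             dose_corr_target = 0.224,
                             infection_beta = 0,
                             infection_base_rate = 119 / 509,
                             infection_sigma_u = 0.8,
                             febrile_given_infection = 20 / 119,
                             nonadherence_patient_fraction = 0.24,
                             nonadherence_month_prob = 0.6,
                             regimen_probs = c(tacrolimus = 39, cyclosporin = 3, rapamycin = 3) / 45,
                             antiprolif_probs = c(MMF = 38, azathioprine = 4, none = 3) / 45,
                             disease_probs = c(CAKUT = 23, glomerular = 5, cystic = 8, nephrotic = 6, metabolic = 2) / 44,
                             donation_probs = c(living = 30, deceased = 15) / 45,
                             male_prob = 31 / 45,
                             dsa_prob = 8 / 45,
                             age_mean = 12.8, age_sd = 5.2,
                             post_tx_mean = 4.5, post_tx_sd = 4.2,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "ttv_gen_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  stopifnot_msg(cfg$n_patients >= 1, "n_patients must be >= 1")
  stopifnot_msg(cfg$n_months >= 1, "n_months must be >= 1")
  for (f in c("visit_missingness", "infection_base_rate", "infection_beta",
              "febrile_given_infection", "nonadherence_patient_fraction",
              "nonadherence_month_prob", "male_prob", "dsa_prob")) {
    v <- cfg[[f]]
    if (f != "infection_beta") {
      stopifnot_msg(is.numeric(v) && v >= 0 && v <= 1,
                    paste(f, "must be a probability in [0,1]"))
    }
  }
  stopifnot_msg(cfg$detection_floor < cfg$ceiling,
                "detection_floor must be below ceiling")
  stopifnot_msg(cfg$ar1_rho >= 0 && cfg$ar1_rho < 1, "ar1_rho must be in [0,1)")
  stopifnot_msg(abs(cfg$dose_corr_target) < 1, "dose_corr_target must be in (-1,1)")
  for (f in c("regimen_probs", "antiprolif_probs", "disease_probs",
              "donation_probs")) {
    pr <- cfg[[f]]
    stopifnot_msg(all(pr >= 0) && abs(sum(pr) - 1) < 1e-8,
                  paste(f, "must be a distribution summing to 1"))
  }
  stopifnot_msg(all(names(cfg$regimen_probs) == REGIMEN_LEVELS) &&
                  all(names(cfg$antiprolif_probs) == ANTIPROLIF_LEVELS),
                "category names must match the schema levels")
  invisible(cfg)
}

# standard AR(1) matrix (rows = patients, cols = months), marginal variance 1
ar1_matrix <- function(n, m, rho) {
  out <- matrix(0, n, m)
  out[, 1] <- stats::rnorm(n)
  if (m > 1) {
    sc <- sqrt(1 - rho^2)
    for (t in 2:m) out[, t] <- rho * out[, t - 1] + sc * stats::rnorm(n)
  }
  out
}

#' Generate a synthetic longitudinal TTV cohort
#'
#' Latent log10 load for patient i at month t:
#' L_it = baseline + regimen effect + post_tx_slope * (post-transplant years)
#' + b_i + eps_it, with b_i ~ Normal(0, between_patient_sd^2) and eps_it an
#' AR(1) monthly fluctuation that shares a latent component with the
#' prednisolone dose series to induce the configured within-patient rank
#' correlation. The observed raw load is 0 when L_it falls below the
#' detection floor and 10^min(L_it, ceiling) otherwise. Infection flags are
#' Bernoulli on the logit scale with slope \code{infection_beta} per log10 of
#' the observed load and a patient-level random intercept, so injected
#' effects are recovered by the corresponding analysis module.
#'
#' @param config a [generator_config()].
#' @return a validated \code{ttv_cohort}.
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  m <- config$n_months

  pid <- sprintf("P%03d", seq_len(n))
  gender <- ifelse(stats::runif(n) < config$male_prob, "male", "female")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 1.5), 19.5)
  post_tx <- pmax(stats::rnorm(n, config$post_tx_mean, config$post_tx_sd), 0.3)
  post_tx <- pmin(post_tx, pmax(age - 0.5, 0.3))
  age_tx <- pmax(age - post_tx, 0.1)
  regimen <- sample(names(config$regimen_probs), n, TRUE, config$regimen_probs)
  antiprolif <- sample(names(config$antiprolif_probs), n, TRUE,
                       config$antiprolif_probs)
  disease <- sample(names(config$disease_probs), n, TRUE, config$disease_probs)
  donation <- sample(names(config$donation_probs), n, TRUE,
                     config$donation_probs)
  mismatch <- sample(0:6, n, TRUE, prob = c(.02, .08, .30, .40, .12, .06, .02))
  dsa <- stats::runif(n) < config$dsa_prob

  patients <- data.frame(
    patient_id = pid, gender = gender,
    age_at_study_start = round(age, 1),
    age_at_transplant = round(age_tx, 1),
    post_transplant_time = round(post_tx, 2),
    primary_disease = disease, donation_type = donation,
    hla_mismatch = mismatch, dsa_positive = dsa,
    cni_or_mtori = regimen, antiproliferative = antiprolif,
    stringsAsFactors = FALSE
  )

  # latent load: patient level + shared/idiosyncratic AR(1) monthly noise
  b <- stats::rnorm(n, 0, config$between_patient_sd)
  z_shared <- ar1_matrix(n, m, config$ar1_rho)
  w_own <- ar1_matrix(n, m, config$ar1_rho)
  a <- 2 * sin(pi * config$dose_corr_target / 6)  # Pearson loading for the
                                                  # target Spearman rho
  eps <- config$within_patient_sd * (a * z_shared + sqrt(1 - a^2) * w_own)
  mu_i <- config$baseline_mean +
    ifelse(regimen == "rapamycin", config$mtori_effect, 0) +
    config$post_tx_slope * post_tx + b
  L <- mu_i + eps                                  # n x m latent log10 loads

  observed <- matrix(stats::runif(n * m) >= config$visit_missingness, n, m)

  # monthly covariates
  pred_dose <- pmax(5 + 1.2 * z_shared, 0)          # mg/m2, monotone in the
                                                    # shared process
  tac_dose <- 0.15 + 0.03 * ar1_matrix(n, m, config$ar1_rho)
  cyc_dose <- 5 + 0.8 * ar1_matrix(n, m, config$ar1_rho)
  rap_dose <- 0.06 + 0.012 * ar1_matrix(n, m, config$ar1_rho)
  mmf_dose <- 1100 + 150 * ar1_matrix(n, m, config$ar1_rho)
  aza_dose <- 1.5 + 0.25 * ar1_matrix(n, m, config$ar1_rho)
  tac_trough <- pmax(6 + 1.8 * ar1_matrix(n, m, config$ar1_rho), 0.5)
  cyc_trough <- pmax(90 + 25 * ar1_matrix(n, m, config$ar1_rho), 5)
  rap_trough <- pmax(6 + 1.5 * ar1_matrix(n, m, config$ar1_rho), 0.5)
  egfr <- pmax(75 + 18 * matrix(stats::rnorm(n), n, m) +
                 8 * ar1_matrix(n, m, config$ar1_rho), 10)
  covirus <- function() {
    lat <- 0.5 + 1.5 * ar1_matrix(n, m, config$ar1_rho)
    ifelse(lat < 2, 0, pmin(lat, 8))               # same LOD convention
  }
  ebv <- covirus(); cmv <- covirus(); bkv <- covirus()

  # observed load with detection-limit censoring
  Lc <- pmin(L, config$ceiling)
  ttv_raw <- ifelse(L < config$detection_floor, 0, 10^Lc)
  ttv_log10_obs <- ifelse(L < config$detection_floor, 0, Lc)

  # events on the observed-load scale
  alpha_inf <- stats::qlogis(config$infection_base_rate) -
    config$infection_beta * mean(ttv_log10_obs)
  u_inf <- stats::rnorm(n, 0, config$infection_sigma_u)
  p_inf <- stats::plogis(alpha_inf + config$infection_beta * ttv_log10_obs +
                           matrix(u_inf, n, m))
  infection <- matrix(stats::runif(n * m) < p_inf, n, m)
  febrile <- infection &
    matrix(stats::runif(n * m) < config$febrile_given_infection, n, m)
  nonadh_type <- stats::runif(n) < config$nonadherence_patient_fraction
  nonadh <- matrix(nonadh_type, n, m) &
    matrix(stats::runif(n * m) < config$nonadherence_month_prob, n, m)

  idx <- which(observed, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]; t <- idx[, 2]
  pick <- function(mat) mat[cbind(i, t)]
  on <- function(mat, drug, who) ifelse(who[i] == drug, pick(mat), NA_real_)

  visits <- data.frame(
    patient_id = pid[i],
    month_index = t - 1L,
    ttv_raw = pick(ttv_raw),
    prednisolone_dose = round(pick(pred_dose), 2),
    tacrolimus_dose = round(on(tac_dose, "tacrolimus", regimen), 3),
    cyclosporin_dose = round(on(cyc_dose, "cyclosporin", regimen), 2),
    rapamycin_dose = round(on(rap_dose, "rapamycin", regimen), 4),
    mmf_dose = round(on(mmf_dose, "MMF", antiprolif), 0),
    azathioprine_dose = round(on(aza_dose, "azathioprine", antiprolif), 2),
    tacrolimus_trough = round(on(tac_trough, "tacrolimus", regimen), 1),
    cyclosporin_trough = round(on(cyc_trough, "cyclosporin", regimen), 0),
    rapamycin_trough = round(on(rap_trough, "rapamycin", regimen), 1),
    egfr = round(pick(egfr), 1),
    ebv_log10 = round(pick(ebv), 2),
    cmv_log10 = round(pick(cmv), 2),
    bkv_log10 = round(pick(bkv), 2),
    infection = pick(infection),
    febrile_infection = pick(febrile),
    nonadherence_suspected = pick(nonadh),
    stringsAsFactors = FALSE
  )

  new_cohort(patients, visits)
}

#' Named fixture cohorts for tests and worked examples
#'
#' \describe{
#'   \item{tiny}{2 patients x 3 visits with distinct hand-set values, small
#'     enough for exhaustive-permutation oracles ((3!)^2 = 36 joint
#'     within-patient permutations).}
#'   \item{null}{default-sized cohort with the dose-load coupling and the
#'     infection slope both switched off.}
#'   \item{dose_effect}{default-sized cohort with a within-patient dose-load
#'     Spearman correlation of 0.25 injected.}
#'   \item{infection_effect}{default-sized cohort with an infection log-odds
#'     slope of 0.5 per log10 TTV and patient intercept SD 1.}
#' }
#'
#' @param name one of "tiny", "null", "dose_effect", "infection_effect".
#' @return list with elements \code{cohort} and \code{truth} (every injected
#'   parameter).
#' @export
make_fixture <- function(name = c("tiny", "null", "dose_effect",
                                  "infection_effect")) {
  name <- match.arg(name)
  if (name == "tiny") {
    patients <- data.frame(
      patient_id = c("T01", "T02"),
      gender = c("male", "female"),
      age_at_study_start = c(10, 14),
      age_at_transplant = c(6, 9),
      post_transplant_time = c(4, 5),
      primary_disease = c("CAKUT", "cystic"),
      donation_type = c("living", "deceased"),
      hla_mismatch = c(3L, 2L),
      dsa_positive = c(FALSE, TRUE),
      cni_or_mtori = c("tacrolimus", "tacrolimus"),
      antiproliferative = c("MMF", "none"),
      stringsAsFactors = FALSE
    )
    visits <- data.frame(
      patient_id = rep(c("T01", "T02"), each = 3),
      month_index = rep(0:2, 2),
      ttv_raw = c(10^4.1, 10^5.3, 10^6.2, 10^3.4, 10^5.9, 10^4.8),
      prednisolone_dose = c(3.1, 4.7, 5.6, 2.2, 6.1, 3.9),
      tacrolimus_dose = c(0.12, 0.14, 0.13, 0.16, 0.15, 0.17),
      cyclosporin_dose = NA_real_, rapamycin_dose = NA_real_,
      mmf_dose = c(1100, 1150, 1120, NA, NA, NA),
      azathioprine_dose = NA_real_,
      tacrolimus_trough = c(6.1, 5.8, 7.0, 6.5, 5.2, 6.8),
      cyclosporin_trough = NA_real_, rapamycin_trough = NA_real_,
      egfr = c(80, 76, 82, 65, 70, 68),
      ebv_log10 = 0, cmv_log10 = 0, bkv_log10 = 0,
      infection = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
      febrile_infection = FALSE,
      nonadherence_suspected = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE
    )
    return(list(cohort = new_cohort(patients, visits),
                truth = list(dose_corr_target = NA_real_,
                             infection_beta = NA_real_)))
  }
  cfg <- switch(
    name,
    null = generator_config(dose_corr_target = 0, infection_beta = 0,
                            seed = 20201L),
    dose_effect = generator_config(dose_corr_target = 0.25, seed = 20202L),
    infection_effect = generator_config(infection_beta = 0.5,
                                        infection_sigma_u = 1,
                                        seed = 20203L)
  )
  list(cohort = generate_cohort(cfg), truth = unclass(cfg))
}
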