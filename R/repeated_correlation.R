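#' Spearman rank correlation with midrank ties
#'
#' Pearson correlation of midranks (average ranks for ties), after pairwise
#' deletion of incomplete pairs. Undefined cases — fewer than 3 complete
#' pairs, or either series constant — return \code{NA}; the caller decides
#' whether the patient contributes.
#'
#' @param x,y numeric series of equal length.
#' @return rho in [-1, 1], or \code{NA} when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- rx - mean(rx); sy <- ry - mean(ry)
  dx <- sqrt(sum(sx^2)); dy <- sqrt(sum(sy^2))
  if (dx == 0 || dy == 0) return(NA_real_)  # constant series
  sum(sx * sy) / (dx * dy)
}

# Complete (TTV, covariate) pair series per patient, for one monthly metric.
# Returns a list of data.frames (x = ttv_log10, y = covariate), keeping only
# patients with >= min_pairs complete pairs. Patients never measured on the
# covariate (e.g. not on that drug) drop out through missingness.
patient_pair_series <- function(cohort, variable, min_pairs = 3) {
  v <- cohort$visits
  if (!variable %in% names(v)) stop("unknown monthly variable: ", variable)
  keep <- !is.na(v$ttv_log10) & !is.na(v[[variable]])
  v <- v[keep, c("patient_id", "month_index", "ttv_log10", variable)]
  series <- split(v, v$patient_id)
  series <- series[vapply(series, nrow, integer(1)) >= min_pairs]
  lapply(series, function(d) {
    d <- d[order(d$month_index), ]
    data.frame(x = d$ttv_log10, y = d[[variable]])
  })
}

#' Per-patient Spearman correlations of TTV with a monthly covariate
#'
#' Computes [spearman_rho()] between each patient's monthly log10 TTV series
#' and a monthly metric covariate (a drug dose, trough level, co-virus load
#' or eGFR). Only patients with at least \code{min_pairs} complete pairs and
#' a defined rho contribute; for drug-specific variables this restricts the
#' map to patients on that drug, because other patients' dose columns are
#' missing by schema.
#'
#' @param cohort a \code{ttv_cohort}.
#' @param variable name of a monthly visit column.
#' @param min_pairs minimum complete pairs per patient (default 3, the
#'   smallest series with a nondegenerate rank correlation).
#' @return named numeric vector: patient_id -> rho.
#' @export
per_patient_correlations <- function(cohort, variable, min_pairs = 3) {
  series <- patient_pair_series(cohort, variable, min_pairs)
  rho <- vapply(series, function(d) spearman_rho(d$x, d$y), numeric(1))
  rho <- rho[!is.na(rho)]
  if (length(rho) == 0) {
    stop("no patient has a defined TTV correlation for ", variable)
  }
  rho
}

# Centered, unit-norm midrank vector (NA if degenerate).
normalized_ranks <- function(v) {
  r <- rank(v, ties.method = "average")
  c0 <- r - mean(r)
  nrm <- sqrt(sum(c0^2))
  if (nrm == 0) return(NULL)
  c0 / nrm
}

#' Within-patient permutation test of the mean repeated-measures correlation
#'
#' The test statistic is the unweighted mean, across patients, of the
#' per-patient Spearman correlation between monthly TTV load and the
#' covariate. The null distribution is generated by independently permuting,
#' within each patient, the time order of the covariate series while holding
#' the TTV series fixed — the minimal exchangeability assumption targeting
#' the within-patient association — and recomputing the mean each iteration.
#' The two-sided p-value uses the add-one correction,
#' p = (#\{|T*| >= |T|\} + 1) / (B + 1), so it is valid at finite B and can
#' never fall below 1/(B + 1). Patients with an undefined rho (constant
#' series, too few pairs) are excluded from both the observed and the
#' permuted statistic, so both use the same patient set.
#'
#' @param cohort a \code{ttv_cohort}.
#' @param variable name of a monthly visit column.
#' @param n_permutations number of permutation iterations (study default
#'   10000).
#' @param seed integer seed; the whole result is reproducible given the seed.
#' @param min_pairs minimum complete pairs per patient.
#' @return a \code{ttv_correlation}: variable, per_patient_rho (named),
#'   mean_rho, p_value, n_patients, n_permutations, seed.
#' @export
mean_correlation_permutation_test <- function(cohort, variable,
                                              n_permutations = 10000,
                                              seed = 1, min_pairs = 3) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  series <- patient_pair_series(cohort, variable, min_pairs)
  rx <- lapply(series, function(d) normalized_ranks(d$x))
  ry <- lapply(series, function(d) normalized_ranks(d$y))
  ok <- !vapply(rx, is.null, logical(1)) & !vapply(ry, is.null, logical(1))
  rx <- rx[ok]; ry <- ry[ok]
  if (length(rx) < 2) {
    stop("fewer than 2 patients contribute a defined correlation for ",
         variable)
  }
  # rho = dot product of the two unit-norm centered rank vectors; permuting
  # the raw covariate series permutes its midranks, so the null only ever
  # permutes ry.
  obs_rho <- mapply(function(a, b) sum(a * b), rx, ry)
  t_obs <- mean(obs_rho)
  set.seed(seed)
  t_null <- perm_mean_rho(rx, ry, as.integer(n_permutations))
  p <- (sum(abs(t_null) >= abs(t_obs) - 1e-12) + 1) / (n_permutations + 1)
  structure(list(variable = variable,
                 per_patient_rho = obs_rho,
                 mean_rho = t_obs,
                 p_value = p,
                 n_patients = length(obs_rho),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "ttv_correlation")
}

#' @export
print.ttv_correlation <- function(x, ...) {
  cat(sprintf("%s: mean rho = %.3f over %d patients, p = %.4g (B = %d)\n",
              x$variable, x$mean_rho, x$n_patients, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Repeated-measures correlation scan (the Table-3-style analysis)
#'
#' Runs the permutation test for every monthly metric covariate: the six drug
#' doses, the three trough levels, the three co-virus loads and eGFR.
#' Variables with too few eligible patients are reported as skipped.
#'
#' @param cohort a \code{ttv_cohort}.
#' @param n_permutations iterations per variable (default 10000).
#' @param seed base seed; variable k uses seed + k so tests are independent
#'   yet reproducible.
#' @param min_pairs minimum complete pairs per patient.
#' @return named list of \code{ttv_correlation} (or skip records).
#' @export
run_correlation_scan <- function(cohort, n_permutations = 10000, seed = 1,
                                 min_pairs = 3) {
  vars <- c("prednisolone_dose", "tacrolimus_dose", "cyclosporin_dose",
            "rapamycin_dose", "mmf_dose", "azathioprine_dose",
            "tacrolimus_trough", "cyclosporin_trough", "rapamycin_trough",
            "ebv_log10", "cmv_log10", "bkv_log10", "egfr")
  out <- lapply(seq_along(vars), function(k) {
    tryCatch(
      mean_correlation_permutation_test(cohort, vars[k],
                                        n_permutations = n_permutations,
                                        seed = seed + k,
                                        min_pairs = min_pairs),
      error = function(e) structure(list(variable = vars[k],
                                         message = conditionMessage(e)),
                                    class = "ttv_skipped")
    )
  })
  stats::setNames(out, vars)
}
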