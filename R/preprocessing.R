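#' Left-censored log10 viral-load transform
#'
#' Raw TTV copy numbers of 0 encode a sample below the assay detection limit
#' (2 log10 copies/ml). Such values are set to 1 before the log10 transform,
#' so an undetectable sample maps to log10(1) = 0, keeping the transformed
#' scale in \{0\} U [2, 10]. The assay cannot report fractional copies below
#' one, so raw values strictly between 0 and 1 are a domain error.
#'
#' @param raw numeric vector of copies/ml, each 0 or >= 1 (NA passed through).
#' @return log10 copies/ml: 0 for undetectable samples, log10(raw) otherwise.
#' @examples
#' log10_viral_load(c(0, 100, 630957))
#' @export
log10_viral_load <- function(raw) {
  bad_neg <- !is.na(raw) & raw < 0
  if (any(bad_neg)) stop("negative viral load: ", raw[bad_neg][1])
  bad_gap <- !is.na(raw) & raw > 0 & raw < 1
  if (any(bad_gap)) {
    stop("raw viral load in (0,1) is impossible for this assay: ",
         raw[bad_gap][1])
  }
  out <- raw
  out[!is.na(raw)] <- log10(pmax(raw[!is.na(raw)], 1))
  out
}

#' Original Schwartz estimate of GFR
#'
#' eGFR = k * height(cm) / serum creatinine(mg/dl), in ml/min/1.73 m2. The
#' constant k depends on age and gender; [schwartz_k()] supplies the
#' conventional defaults when the caller does not.
#'
#' @param height_cm body height in cm, > 0.
#' @param serum_creatinine serum creatinine in mg/dl, > 0.
#' @param k Schwartz constant (unitless); see [schwartz_k()].
#' @return eGFR in ml/min/1.73 m2.
#' @export
schwartz_egfr <- function(height_cm, serum_creatinine, k) {
  if (any(!is.na(height_cm) & height_cm <= 0)) stop("height must be positive")
  if (any(!is.na(serum_creatinine) & serum_creatinine <= 0)) {
    stop("serum creatinine must be positive")
  }
  if (any(!is.na(k) & k <= 0)) stop("Schwartz k must be positive")
  k * height_cm / serum_creatinine
}

#' Default Schwartz constant by age and gender
#'
#' 0.45 for infants under 1 year, 0.70 for adolescent males (age >= 13),
#' 0.55 otherwise (children and adolescent females).
#'
#' @param age_years age in years.
#' @param gender "male" or "female".
#' @return the constant k.
#' @export
schwartz_k <- function(age_years, gender) {
  ifelse(age_years < 1, 0.45,
         ifelse(age_years >= 13 & gender == "male", 0.70, 0.55))
}

#' Per-patient summary of the 12-month TTV series
#'
#' The patient-level analyses work on the arithmetic mean of the transformed
#' log10 loads across all of a patient's time points. Undetectable samples
#' enter the mean as 0 (they were transformed, not removed); months with no
#' measurement are simply absent and contribute nothing.
#'
#' @param visits the visit rows of one patient (with \code{ttv_log10}).
#' @return one-row data.frame: \code{patient_id}, \code{mean_ttv_log10},
#'   \code{n_visits} (non-missing measurements), \code{n_detectable}
#'   (measurements above the detection limit).
#' @export
summarize_patient <- function(visits) {
  pid <- unique(visits$patient_id)
  if (length(pid) != 1) stop("visits must belong to exactly one patient")
  lg <- visits$ttv_log10[!is.na(visits$ttv_log10)]
  if (length(lg) == 0) {
    stop("patient ", pid, " has no usable TTV measurement")
  }
  data.frame(patient_id = pid,
             mean_ttv_log10 = mean(lg),
             n_visits = length(lg),
             n_detectable = sum(lg > 0),
             stringsAsFactors = FALSE)
}

#' Per-patient summaries for a whole cohort
#'
#' @param cohort a \code{ttv_cohort}.
#' @return data.frame with one [summarize_patient()] row per patient that has
#'   at least one usable measurement, in patient-table order.
#' @export
summarize_cohort <- function(cohort) {
  v <- cohort$visits
  keep <- !is.na(v$ttv_log10)
  rows <- lapply(split(v[keep, , drop = FALSE], v$patient_id[keep]),
                 summarize_patient)
  out <- do.call(rbind, rows)
  out <- out[match(intersect(cohort$patients$patient_id, out$patient_id),
                   out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of samples with detectable viral DNA
#'
#' @param n_detectable number of samples above the detection limit.
#' @param n_samples total number of assessed samples.
#' @return percentage on the 0-100 scale.
#' @examples
#' detectable_percent(481, 509)  # 94.5 (to one decimal)
#' @export
detectable_percent <- function(n_detectable, n_samples) {
  if (any(n_samples <= 0)) stop("n_samples must be positive")
  if (any(n_detectable < 0 | n_detectable > n_samples)) {
    stop("n_detectable must lie in [0, n_samples]")
  }
  100 * n_detectable / n_samples
}

#' Cohort-level prevalence and viral-load summary
#'
#' Counts assessed samples, the fraction with detectable TTV DNA, and the
#' median / interquartile range of the detectable log10 loads.
#'
#' @param cohort a \code{ttv_cohort}.
#' @return list: n_samples, n_detectable, percent_detectable, median_log10,
#'   iqr_log10 (length-2).
#' @export
prevalence_summary <- function(cohort) {
  lg <- cohort$visits$ttv_log10
  lg <- lg[!is.na(lg)]
  det <- lg[lg > 0]
  list(n_samples = length(lg),
       n_detectable = length(det),
       percent_detectable = detectable_percent(length(det), length(lg)),
       median_log10 = stats::median(det),
       iqr_log10 = unname(stats::quantile(det, c(0.25, 0.75))))
}

#' Lag the TTV predictor one month ahead of a binary outcome
#'
#' Pairs the TTV load at month m with an event flag at month m + 1, for the
#' "load one month before onset" analysis. A pair is emitted only when both
#' calendar months are present and both fields non-missing; gaps break the
#' chain (strictly adjacent months, no tolerance window).
#'
#' @param visits one patient's visit rows, any order.
#' @param outcome_field name of a logical visit column.
#' @return data.frame \code{patient_id}, \code{month_index} (predictor month),
#'   \code{ttv_log10}, \code{outcome}; zero rows allowed.
#' @export
build_lagged_pairs <- function(visits, outcome_field) {
  if (!outcome_field %in% names(visits)) {
    stop("unknown outcome field: ", outcome_field)
  }
  v <- visits[order(visits$month_index), , drop = FALSE]
  idx <- match(v$month_index + 1L, v$month_index)
  ok <- !is.na(idx) & !is.na(v$ttv_log10) & !is.na(v[[outcome_field]][idx])
  data.frame(patient_id = v$patient_id[ok],
             month_index = v$month_index[ok],
             ttv_log10 = v$ttv_log10[ok],
             outcome = as.integer(v[[outcome_field]][idx][ok]),
             stringsAsFactors = FALSE)
}
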