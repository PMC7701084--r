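#' @useDynLib ttvload, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov lm anova coef vcov pnorm pt pf qnorm rnorm runif rbinom
#'   sd var complete.cases plogis qlogis glm binomial optim optimHess median
#'   quantile setNames cor
#' @importFrom utils read.csv write.csv
NULL

# Column schemas shared by the reader, writer and generator.
PATIENT_COLS <- c(
  "patient_id", "gender", "age_at_study_start", "age_at_transplant",
  "post_transplant_time", "primary_disease", "donation_type",
  "hla_mismatch", "dsa_positive", "cni_or_mtori", "antiproliferative"
)

VISIT_COLS <- c(
  "patient_id", "month_index", "ttv_raw",
  "prednisolone_dose", "tacrolimus_dose", "cyclosporin_dose",
  "rapamycin_dose", "mmf_dose", "azathioprine_dose",
  "tacrolimus_trough", "cyclosporin_trough", "rapamycin_trough",
  "egfr", "ebv_log10", "cmv_log10", "bkv_log10",
  "infection", "febrile_infection", "nonadherence_suspected"
)

GENDER_LEVELS <- c("male", "female")
DISEASE_LEVELS <- c("CAKUT", "glomerular", "cystic", "nephrotic", "metabolic")
DONATION_LEVELS <- c("living", "deceased")
REGIMEN_LEVELS <- c("tacrolimus", "cyclosporin", "rapamycin")
ANTIPROLIF_LEVELS <- c("MMF", "azathioprine", "none")

# Dose/trough columns tied to a maintenance regimen or anti-proliferative
# agent: they may be non-missing only in visits of patients on that drug.
REGIMEN_DRUG_COLS <- list(
  tacrolimus  = c("tacrolimus_dose", "tacrolimus_trough"),
  cyclosporin = c("cyclosporin_dose", "cyclosporin_trough"),
  rapamycin   = c("rapamycin_dose", "rapamycin_trough")
)
ANTIPROLIF_DRUG_COLS <- list(
  MMF = "mmf_dose",
  azathioprine = "azathioprine_dose",
  none = character(0)
)

#' Assemble and validate a longitudinal TTV cohort
#'
#' A cohort couples a patient-level table (fixed covariates: demographics,
#' transplant characteristics, immunosuppressive regimen) with a long-format
#' visit table (one row per patient-month: raw TTV copies/ml, drug doses and
#' trough levels, eGFR, co-virus loads, binary event flags). The log10 TTV
#' load is derived from \code{ttv_raw} via [log10_viral_load()] and is never
#' stored on disk.
#'
#' @param patients data.frame with columns \code{patient_id}, \code{gender},
#'   \code{age_at_study_start}, \code{age_at_transplant},
#'   \code{post_transplant_time}, \code{primary_disease},
#'   \code{donation_type}, \code{hla_mismatch}, \code{dsa_positive},
#'   \code{cni_or_mtori}, \code{antiproliferative}.
#' @param visits data.frame in the visit schema (see Details); a derived
#'   \code{ttv_log10} column, if present, is recomputed.
#' @param validate if \code{TRUE} (default) run the full invariant check.
#' @return An object of class \code{ttv_cohort}: a list with elements
#'   \code{patients} and \code{visits} (the latter carrying \code{ttv_log10}).
#' @details Invariants enforced: unique \code{patient_id}; unique
#'   \code{(patient_id, month_index)}; post-transplant time of at least 0.25
#'   years (the study excluded patients transplanted less than 3 months
#'   before); \code{febrile_infection} implies \code{infection};
#'   \code{ttv_log10} in \{0\} or [2, 10] (assay reportable range, with 0
#'   encoding below the 2 log10 copies/ml detection limit); dose and trough
#'   columns of drugs a patient is not on are missing, never zero-filled.
#' @export
new_cohort <- function(patients, visits, validate = TRUE) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  missing_p <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_p) > 0) {
    stop("patient table lacks columns: ", paste(missing_p, collapse = ", "))
  }
  missing_v <- setdiff(VISIT_COLS, names(visits))
  if (length(missing_v) > 0) {
    stop("visit table lacks columns: ", paste(missing_v, collapse = ", "))
  }
  patients <- patients[PATIENT_COLS]
  visits <- visits[VISIT_COLS]
  visits$ttv_log10 <- log10_viral_load(visits$ttv_raw)
  cohort <- structure(list(patients = patients, visits = visits),
                      class = "ttv_cohort")
  if (validate) validate_cohort(cohort)
  cohort
}

#' Validate a cohort against the schema invariants
#'
#' @param cohort a \code{ttv_cohort}.
#' @return The cohort, invisibly; stops with a descriptive error on the first
#'   violated invariant.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  v <- cohort$visits

  dup <- p$patient_id[duplicated(p$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_gender <- setdiff(stats::na.omit(unique(p$gender)), GENDER_LEVELS)
  if (length(bad_gender) > 0) stop("unknown gender level: ", bad_gender[1])
  bad_dis <- setdiff(stats::na.omit(unique(p$primary_disease)), DISEASE_LEVELS)
  if (length(bad_dis) > 0) stop("unknown primary_disease level: ", bad_dis[1])
  bad_don <- setdiff(stats::na.omit(unique(p$donation_type)), DONATION_LEVELS)
  if (length(bad_don) > 0) stop("unknown donation_type level: ", bad_don[1])
  bad_reg <- setdiff(stats::na.omit(unique(p$cni_or_mtori)), REGIMEN_LEVELS)
  if (length(bad_reg) > 0) stop("unknown cni_or_mtori level: ", bad_reg[1])
  bad_ap <- setdiff(stats::na.omit(unique(p$antiproliferative)), ANTIPROLIF_LEVELS)
  if (length(bad_ap) > 0) stop("unknown antiproliferative level: ", bad_ap[1])

  short_ptt <- !is.na(p$post_transplant_time) & p$post_transplant_time < 0.25
  if (any(short_ptt)) {
    stop("post_transplant_time below 0.25 years for patient ",
         p$patient_id[which(short_ptt)[1]],
         " (patients under 3 months post-transplant are excluded)")
  }
  bad_mm <- !is.na(p$hla_mismatch) &
    (p$hla_mismatch < 0 | p$hla_mismatch != round(p$hla_mismatch))
  if (any(bad_mm)) {
    stop("hla_mismatch must be a non-negative integer count (patient ",
         p$patient_id[which(bad_mm)[1]], ")")
  }

  key <- paste(v$patient_id, v$month_index, sep = "\r")
  dupv <- duplicated(key)
  if (any(dupv)) {
    stop("duplicate (patient_id, month_index) visit key: ",
         gsub("\r", ", month ", key[which(dupv)[1]]))
  }
  orphan <- setdiff(unique(v$patient_id), p$patient_id)
  if (length(orphan) > 0) {
    stop("visit references unknown patient: ", orphan[1])
  }
  bad_month <- !is.na(v$month_index) &
    (v$month_index < 0 | v$month_index != round(v$month_index))
  if (any(bad_month)) stop("month_index must be a non-negative integer")

  lg <- v$ttv_log10
  bad_lg <- !is.na(lg) & !(lg == 0 | (lg >= 2 & lg <= 10))
  if (any(bad_lg)) {
    i <- which(bad_lg)[1]
    stop("ttv_log10 outside {0} U [2, 10] (value ", format(lg[i]),
         ", patient ", v$patient_id[i], ", month ", v$month_index[i], ")")
  }

  fe <- !is.na(v$febrile_infection) & v$febrile_infection &
    (is.na(v$infection) | !v$infection)
  if (any(fe)) {
    i <- which(fe)[1]
    stop("febrile_infection without infection (patient ", v$patient_id[i],
         ", month ", v$month_index[i], ")")
  }

  # regimen category constrains which drug columns may carry data
  reg <- p$cni_or_mtori[match(v$patient_id, p$patient_id)]
  for (drug in names(REGIMEN_DRUG_COLS)) {
    for (col in REGIMEN_DRUG_COLS[[drug]]) {
      off <- !is.na(reg) & reg != drug & !is.na(v[[col]])
      if (any(off)) {
        i <- which(off)[1]
        stop(col, " present for patient ", v$patient_id[i],
             " who is not on ", drug)
      }
    }
  }
  ap <- p$antiproliferative[match(v$patient_id, p$patient_id)]
  off_mmf <- !is.na(ap) & ap != "MMF" & !is.na(v$mmf_dose)
  if (any(off_mmf)) {
    stop("mmf_dose present for patient ", v$patient_id[which(off_mmf)[1]],
         " who is not on MMF")
  }
  off_aza <- !is.na(ap) & ap != "azathioprine" & !is.na(v$azathioprine_dose)
  if (any(off_aza)) {
    stop("azathioprine_dose present for patient ",
         v$patient_id[which(off_aza)[1]], " who is not on azathioprine")
  }

  invisible(cohort)
}

#' Read a cohort from its two CSV tables
#'
#' Missing values are empty cells; "0" is legal only where zero is meaningful
#' (\code{ttv_raw}, where it encodes below-detection, and doses of drugs the
#' patient actually takes). \code{ttv_log10} is recomputed on load, never read.
#'
#' @param patient_table_path path to patients.csv.
#' @param visit_table_path path to visits.csv.
#' @return A validated \code{ttv_cohort}.
#' @export
read_cohort <- function(patient_table_path, visit_table_path) {
  for (path in c(patient_table_path, visit_table_path)) {
    if (!file.exists(path)) stop("file not found: ", path)
  }
  patients <- utils::read.csv(patient_table_path, stringsAsFactors = FALSE,
                              na.strings = "")
  visits <- utils::read.csv(visit_table_path, stringsAsFactors = FALSE,
                            na.strings = "")
  patients$dsa_positive <- as.logical(patients$dsa_positive)
  for (col in c("infection", "febrile_infection", "nonadherence_suspected")) {
    visits[[col]] <- as.logical(visits[[col]])
  }
  # all-NA columns come back logical; pin the numeric schema explicitly
  num_p <- c("age_at_study_start", "age_at_transplant", "post_transplant_time")
  for (col in num_p) patients[[col]] <- as.numeric(patients[[col]])
  num_v <- setdiff(VISIT_COLS, c("patient_id", "month_index", "infection",
                                 "febrile_infection",
                                 "nonadherence_suspected"))
  for (col in num_v) visits[[col]] <- as.numeric(visits[[col]])
  new_cohort(patients, visits)
}

#' Write a cohort to patients.csv / visits.csv
#'
#' @param cohort a \code{ttv_cohort}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_path <- file.path(dir, "patients.csv")
  v_path <- file.path(dir, "visits.csv")
  visits_out <- cohort$visits[VISIT_COLS]  # ttv_log10 is derived, not stored
  utils::write.csv(cohort$patients, p_path, row.names = FALSE, na = "")
  utils::write.csv(visits_out, v_path, row.names = FALSE, na = "")
  invisible(c(patients = p_path, visits = v_path))
}

#' @export
print.ttv_cohort <- function(x, ...) {
  cat("ttv_cohort:", nrow(x$patients), "patients,",
      nrow(x$visits), "visits\n")
  det <- x$visits$ttv_log10 > 0
  cat(sprintf("  TTV detectable in %d/%d visits (%.1f%%)\n",
              sum(det, na.rm = TRUE), sum(!is.na(det)),
              100 * mean(det, na.rm = TRUE)))
  invisible(x)
}

fmt_num <- function(x) {
  # >= 6 significant digits, stable textual form for deterministic files
  ifelse(is.na(x), "", formatC(x, digits = 8, format = "g"))
}

#' Write result tables as CSV
#'
#' Writes one CSV per result family present: patient-level association tests
#' (\code{table2_associations.csv}), repeated-measures correlations
#' (\code{table3_correlations.csv}) and mixed-model logistic regressions
#' (\code{table4_mixed_logit.csv}). Rows are sorted by variable/outcome name
#' and numeric values carry at least 6 significant digits, so identical result
#' sets produce byte-identical files.
#'
#' @param results a non-empty list of \code{ttv_association},
#'   \code{ttv_correlation} and/or \code{ttv_mixed_logit} objects.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  if (length(results) == 0) stop("empty result collection; nothing to write")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cls <- vapply(results, function(r) class(r)[1], character(1))
  known <- c("ttv_association", "ttv_correlation", "ttv_mixed_logit")
  if (any(!cls %in% known)) {
    stop("unknown result type: ", cls[!cls %in% known][1])
  }
  paths <- character(0)

  assoc <- results[cls == "ttv_association"]
  if (length(assoc) > 0) {
    df <- do.call(rbind, lapply(assoc, function(r) {
      data.frame(variable = r$variable, family = r$family,
                 statistic = fmt_num(r$statistic), effect = fmt_num(r$effect[1]),
                 p_value = fmt_num(r$p_value), n = r$n,
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$variable), , drop = FALSE]
    path <- file.path(out_dir, "table2_associations.csv")
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }

  corr <- results[cls == "ttv_correlation"]
  if (length(corr) > 0) {
    df <- do.call(rbind, lapply(corr, function(r) {
      data.frame(variable = r$variable, mean_rho = fmt_num(r$mean_rho),
                 p_value = fmt_num(r$p_value), n_patients = r$n_patients,
                 n_permutations = r$n_permutations, seed = r$seed,
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$variable), , drop = FALSE]
    path <- file.path(out_dir, "table3_correlations.csv")
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }

  ml <- results[cls == "ttv_mixed_logit"]
  if (length(ml) > 0) {
    df <- do.call(rbind, lapply(ml, function(r) {
      data.frame(outcome = r$outcome, or_estimate = fmt_num(r$or_estimate),
                 or_lower = fmt_num(r$or_lower), or_upper = fmt_num(r$or_upper),
                 p_value = fmt_num(r$p_value), sigma_u = fmt_num(r$sigma_u),
                 n_obs = if (is.null(r$n_obs)) NA_integer_ else r$n_obs,
                 n_patients = if (is.null(r$n_patients)) NA_integer_ else r$n_patients,
                 converged = isTRUE(r$converged),
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$outcome), , drop = FALSE]
    path <- file.path(out_dir, "table4_mixed_logit.csv")
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }

  invisible(paths)
}
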