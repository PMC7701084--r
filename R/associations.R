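#' One-way ANOVA of per-patient mean TTV across groups
#'
#' Classical fixed-effects one-way ANOVA: F with (k - 1, n - k) degrees of
#' freedom. For a binary covariate this is equivalent to the pooled-variance
#' two-sample t test (F = t^2). Groups left empty after missing-data removal
#' are dropped with a warning.
#'
#' @param values per-patient mean log10 TTV loads.
#' @param groups group labels, same length as \code{values}; NA pairs are
#'   removed.
#' @param variable name recorded in the result.
#' @return a \code{ttv_association}: variable, family = "anova", statistic
#'   (F), effect (named group means), p_value, n.
#' @export
one_way_anova <- function(values, groups, variable = "covariate") {
  labelled <- unique(as.character(groups[!is.na(groups)]))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  dropped <- setdiff(labelled, unique(groups))
  if (length(dropped) > 0) {
    warning("dropping empty group(s): ", paste(dropped, collapse = ", "))
  }
  k <- length(unique(groups))
  n <- length(values)
  if (k < 2) stop("fewer than 2 non-empty groups for ", variable)
  if (n <= k) stop("need more observations than groups for ", variable)
  gmeans <- tapply(values, groups, mean)
  if (max(gmeans) - min(gmeans) < 1e-12) {
    # no between-group variance: F = 0 by convention (avoids 0/0 when the
    # within-group variance is also zero)
    f_stat <- 0; p <- 1
  } else {
    fit <- stats::aov(values ~ factor(groups))
    s <- summary(fit)[[1]]
    f_stat <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
  }
  structure(list(variable = variable,
                 family = "anova",
                 statistic = f_stat,
                 effect = gmeans,
                 p_value = p,
                 n = n),
            class = "ttv_association")
}

#' Simple linear regression of per-patient mean TTV on a continuous covariate
#'
#' Ordinary least squares; the two-sided p-value for the slope comes from the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param x per-patient covariate values.
#' @param y per-patient mean log10 TTV loads.
#' @param variable name recorded in the result.
#' @return a \code{ttv_association}: variable, family = "linear_regression",
#'   statistic (slope t), effect (slope), p_value, n.
#' @export
simple_linear_regression <- function(x, y, variable = "covariate") {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs for ", variable)
  if (length(unique(x)) < 2) stop("constant covariate: ", variable)
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(list(variable = variable,
                 family = "linear_regression",
                 statistic = cf["x", "t value"],
                 effect = cf["x", "Estimate"],
                 p_value = cf["x", "Pr(>|t|)"],
                 n = n),
            class = "ttv_association")
}

#' @export
print.ttv_association <- function(x, ...) {
  cat(sprintf("%s [%s]: stat = %.4g, p = %.4g, n = %d\n",
              x$variable, x$family, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Patient-level association scan (the Table-2-style analysis)
#'
#' Tests each fixed patient covariate against the per-patient mean log10 TTV
#' load: categorical and binary covariates by one-way ANOVA, continuous ones
#' by simple linear regression. Covariates tested: gender, primary disease,
#' donation type, DSA status, CNI- vs mTORi-based regimen, dual vs triple
#' immunosuppression (anti-proliferative agent present or not), age at study
#' begin, age at transplantation, post-transplant time and HLA mismatch
#' count. No covariate adjustment and no multiple-testing correction are
#' applied; p-values are descriptive.
#'
#' @param cohort a \code{ttv_cohort}.
#' @param mismatch_as "continuous" (default: regression on the count) or
#'   "categorical" (ANOVA across counts).
#' @return named list of \code{ttv_association} results; covariates whose
#'   test fails (e.g. a single group present) are returned as a condition
#'   message under their name.
#' @export
run_association_scan <- function(cohort, mismatch_as = c("continuous", "categorical")) {
  mismatch_as <- match.arg(mismatch_as)
  s <- summarize_cohort(cohort)
  p <- cohort$patients[match(s$patient_id, cohort$patients$patient_id), ]
  y <- s$mean_ttv_log10

  regimen_class <- ifelse(p$cni_or_mtori == "rapamycin", "mTORi", "CNI")
  triple <- ifelse(p$antiproliferative == "none", "dual", "triple")

  spec <- list(
    gender = list(family = "anova", x = p$gender),
    primary_disease = list(family = "anova", x = p$primary_disease),
    donation_type = list(family = "anova", x = p$donation_type),
    dsa_positive = list(family = "anova", x = p$dsa_positive),
    cni_vs_mtori = list(family = "anova", x = regimen_class),
    dual_vs_triple_is = list(family = "anova", x = triple),
    age_at_study_start = list(family = "regression", x = p$age_at_study_start),
    age_at_transplant = list(family = "regression", x = p$age_at_transplant),
    post_transplant_time = list(family = "regression", x = p$post_transplant_time),
    hla_mismatch = list(family = if (mismatch_as == "continuous") "regression" else "anova",
                        x = p$hla_mismatch)
  )

  out <- lapply(names(spec), function(nm) {
    item <- spec[[nm]]
    tryCatch(
      if (item$family == "anova") one_way_anova(y, item$x, nm)
      else simple_linear_regression(item$x, y, nm),
      error = function(e) structure(list(variable = nm, message = conditionMessage(e)),
                                    class = "ttv_skipped")
    )
  })
  stats::setNames(out, names(spec))
}
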