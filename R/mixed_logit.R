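#' Gauss-Hermite quadrature specification
#'
#' @param n_nodes number of quadrature nodes (>= 5; odd numbers place a node
#'   at the mode, default 21).
#' @param adaptive if \code{TRUE} (default), center and scale the nodes at
#'   each patient's posterior mode (adaptive Gauss-Hermite), which stays
#'   accurate when the intercept variance is large — as happens for strongly
#'   patient-clustered outcomes such as non-adherence; static quadrature is
#'   available for cross-checks.
#' @return a \code{quad_spec} list.
#' @export
quad_spec <- function(n_nodes = 21, adaptive = TRUE) {
  if (n_nodes < 5) stop("n_nodes must be >= 5")
  structure(list(n_nodes = as.integer(n_nodes), adaptive = isTRUE(adaptive)),
            class = "quad_spec")
}

log1pexp <- function(m) {
  # stable log(1 + exp(m))
  out <- m
  lo <- m <= 30
  out[lo] <- log1p(exp(m[lo]))
  out
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' For patient i with binary responses y_ij and log10 TTV loads x_ij, the
#' model is logit P(y_ij = 1 | u_i) = alpha + beta x_ij + u_i with
#' u_i ~ Normal(0, sigma_u^2). The marginal likelihood integrates u_i out of
#' each patient's Bernoulli product; the integral is evaluated by (optionally
#' adaptive) Gauss-Hermite quadrature.
#'
#' @param alpha intercept (log-odds).
#' @param beta fixed-effect slope per log10 TTV.
#' @param sigma_u random-intercept SD (>= 0).
#' @param x,y,patient numeric predictor, 0/1 response and patient id, one
#'   entry per observation.
#' @param quad a [quad_spec()].
#' @return total marginal log-likelihood (sum over patients).
#' @export
ri_logit_loglik <- function(alpha, beta, sigma_u, x, y, patient,
                            quad = quad_spec()) {
  pid <- factor(patient)
  gh <- pracma::gaussHermite(quad$n_nodes)
  eta0 <- alpha + beta * x
  if (sigma_u < 1e-12) {
    return(sum(y * eta0 - log1pexp(eta0)))
  }
  if (!quad$adaptive) {
    u <- sqrt(2) * sigma_u * gh$x                       # K node offsets
    M <- outer(eta0, u, "+")                            # N x K
    LP <- y * M - log1pexp(M)
    S <- rowsum(LP, pid)                                # P x K
    A <- sweep(S, 2, log(gh$w) - 0.5 * log(pi), "+")
    mx <- apply(A, 1, max)
    return(sum(mx + log(rowSums(exp(A - mx)))))
  }
  # adaptive: Newton for each patient's posterior mode and curvature
  P <- nlevels(pid)
  u_hat <- numeric(P)
  for (it in 1:100) {
    eta <- eta0 + u_hat[pid]
    p1 <- stats::plogis(eta)
    g <- rowsum(y - p1, pid)[, 1] - u_hat / sigma_u^2
    h <- -(rowsum(p1 * (1 - p1), pid)[, 1] + 1 / sigma_u^2)
    step <- g / h
    # damped Newton: the per-patient objective is concave but its curvature
    # is tiny in the logistic tails, so cap the step to stay stable
    step <- sign(step) * pmin(abs(step), 2)
    u_hat <- u_hat - step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- eta0 + u_hat[pid]
  p1 <- stats::plogis(eta)
  s_i <- 1 / sqrt(rowsum(p1 * (1 - p1), pid)[, 1] + 1 / sigma_u^2)
  z <- gh$x; lw <- log(gh$w) + gh$x^2
  U <- u_hat + sqrt(2) * s_i %o% z                     # P x K node positions
  M <- eta0 + U[pid, , drop = FALSE]                   # N x K
  S <- rowsum(y * M - log1pexp(M), pid)                # P x K
  A <- sweep(S - U^2 / (2 * sigma_u^2), 2, lw, "+") -
    0.5 * log(2 * pi) - log(sigma_u)
  mx <- apply(A, 1, max)
  sum(log(sqrt(2) * s_i) + mx + log(rowSums(exp(A - mx))))
}

plain_logistic <- function(x, y) {
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12)))
  cf <- summary(fit)$coefficients
  list(alpha = cf[1, 1], beta = cf[2, 1], se_beta = cf[2, 2],
       separated = !fit$converged || max(abs(cf[, 1])) > 15)
}

#' Fit a random-intercept logistic regression of a binary monthly outcome on
#' TTV load
#'
#' Maximizes the Gauss-Hermite marginal likelihood (see [ri_logit_loglik()])
#' over (alpha, beta, log sigma_u) by quasi-Newton optimization, starting
#' from the plain logistic fit with sigma_u = 0.5. Standard errors come from
#' the inverse of the observed information (numerical Hessian at the
#' maximum); the 95\% confidence interval for the odds ratio is Wald on the
#' log-odds scale, exp(beta +/- 1.96 SE), and the p-value is the two-sided
#' Wald test of beta = 0. When the variance component collapses
#' (sigma_u < 1e-4) the model is refit as a plain logistic regression with
#' sigma_u reported as 0.
#'
#' @param data data.frame with columns \code{patient_id}, \code{ttv_log10}
#'   and \code{outcome} (0/1).
#' @param quad a [quad_spec()].
#' @param outcome_name label recorded in the result.
#' @return a \code{ttv_mixed_logit}: outcome, beta, se_beta, or_estimate,
#'   or_lower, or_upper, p_value, sigma_u, intercept, loglik, n_obs,
#'   n_patients, converged.
#' @export
fit_random_intercept_logit <- function(data, quad = quad_spec(),
                                       outcome_name = "outcome") {
  data <- data[!is.na(data$ttv_log10) & !is.na(data$outcome), , drop = FALSE]
  x <- data$ttv_log10
  y <- as.numeric(data$outcome)
  patient <- data$patient_id
  if (length(unique(patient)) < 2) stop("need at least 2 patients")
  if (all(y == 0) || all(y == 1)) {
    stop("outcome '", outcome_name, "' has a single class; model not identifiable")
  }

  start <- plain_logistic(x, y)
  if (start$separated) {
    stop("quasi-complete separation detected for outcome '", outcome_name,
         "': likelihood is unbounded")
  }

  # with one observation per patient the random intercept is unidentifiable
  # (the marginal likelihood has a flat ridge in (beta, sigma_u)); profile
  # the variance component at its boundary and report the plain logistic fit
  if (max(table(patient)) == 1) {
    ll <- sum(y * (start$alpha + start$beta * x) -
                log1pexp(start$alpha + start$beta * x))
    zval <- start$beta / start$se_beta
    return(structure(list(outcome = outcome_name, beta = start$beta,
                          se_beta = start$se_beta,
                          or_estimate = exp(start$beta),
                          or_lower = exp(start$beta - 1.96 * start$se_beta),
                          or_upper = exp(start$beta + 1.96 * start$se_beta),
                          p_value = 2 * stats::pnorm(-abs(zval)),
                          sigma_u = 0, intercept = start$alpha, loglik = ll,
                          n_obs = length(y),
                          n_patients = length(unique(patient)),
                          converged = TRUE),
                     class = "ttv_mixed_logit"))
  }

  negll <- function(par) {
    val <- -ri_logit_loglik(par[1], par[2], exp(par[3]), x, y, patient, quad)
    if (!is.finite(val)) 1e10 else val
  }
  par0 <- c(start$alpha, start$beta, log(0.5))
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  sigma_u <- exp(opt$par[3])

  # profile the boundary: when the variance component buys no likelihood the
  # MLE sits at sigma_u = 0 and the fit reduces to plain logistic regression
  ll_boundary <- ri_logit_loglik(start$alpha, start$beta, 0, x, y, patient, quad)
  if (ll_boundary >= -opt$value - 1e-6) sigma_u <- 0

  if (sigma_u < 1e-4) {
    # variance component at the boundary: the model reduces to plain logistic
    beta <- start$beta; se <- start$se_beta; alpha <- start$alpha
    sigma_u <- 0
    ll <- ri_logit_loglik(alpha, beta, 0, x, y, patient, quad)
    conv <- TRUE
  } else {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V)[1:2] <= 0)) {
      stop("observed information not invertible for outcome '", outcome_name,
           "' (flat or separated likelihood)")
    }
    alpha <- opt$par[1]; beta <- opt$par[2]
    se <- sqrt(V[2, 2])
    ll <- -opt$value
    conv <- opt$convergence == 0
  }

  zval <- beta / se
  structure(list(outcome = outcome_name,
                 beta = beta,
                 se_beta = se,
                 or_estimate = exp(beta),
                 or_lower = exp(beta - 1.96 * se),
                 or_upper = exp(beta + 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(zval)),
                 sigma_u = sigma_u,
                 intercept = alpha,
                 loglik = ll,
                 n_obs = length(y),
                 n_patients = length(unique(patient)),
                 converged = conv),
            class = "ttv_mixed_logit")
}

#' @export
print.ttv_mixed_logit <- function(x, ...) {
  cat(sprintf("%s: OR = %.3f [%.3f, %.3f], p = %.3g, sigma_u = %.3f (n = %d obs, %d patients)\n",
              x$outcome, x$or_estimate, x$or_lower, x$or_upper, x$p_value,
              x$sigma_u, x$n_obs, x$n_patients))
  invisible(x)
}

#' Fit the four event models (the Table-4-style analysis)
#'
#' One random-intercept logistic model per binary outcome: infection at the
#' same visit, infection in the following month (TTV lagged one month via
#' [build_lagged_pairs()]), febrile infection, and suspected non-adherence.
#' An outcome observed in a single class is reported as not fitted, with the
#' reason; the remaining models proceed.
#'
#' @param cohort a \code{ttv_cohort}.
#' @param quad a [quad_spec()].
#' @return named list of \code{ttv_mixed_logit} (or \code{ttv_skipped}).
#' @export
run_event_models <- function(cohort, quad = quad_spec()) {
  v <- cohort$visits
  same_month <- function(flag) {
    data.frame(patient_id = v$patient_id, ttv_log10 = v$ttv_log10,
               outcome = as.integer(v[[flag]]), stringsAsFactors = FALSE)
  }
  lagged <- do.call(rbind, lapply(split(v, v$patient_id),
                                  build_lagged_pairs,
                                  outcome_field = "infection"))
  datasets <- list(
    infection = same_month("infection"),
    infection_next_month = lagged[, c("patient_id", "ttv_log10", "outcome")],
    fever = same_month("febrile_infection"),
    nonadherence = same_month("nonadherence_suspected")
  )
  out <- lapply(names(datasets), function(nm) {
    tryCatch(fit_random_intercept_logit(datasets[[nm]], quad, nm),
             error = function(e) structure(list(outcome = nm,
                                                message = conditionMessage(e)),
                                           class = "ttv_skipped"))
  })
  stats::setNames(out, names(datasets))
}
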