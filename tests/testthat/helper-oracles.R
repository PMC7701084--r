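# Independent oracles used across the suite. These stay deliberately naive:
# brute force, closed forms, exhaustive enumeration.

# Plain logistic regression by Newton-Raphson on the score equations.
newton_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    g <- crossprod(X, y - p)
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  p <- 1 / (1 + exp(-drop(X %*% b)))
  V <- solve(crossprod(X, X * p * (1 - p)))
  list(alpha = b[1], beta = b[2], se_beta = sqrt(V[2, 2]))
}

# Marginal log-likelihood of the random-intercept logistic model by fine
# trapezoid integration of each patient's integrand over u in [-8, 8] sigma.
trapezoid_ri_loglik <- function(alpha, beta, sigma_u, x, y, patient,
                                n_grid = 20001) {
  total <- 0
  for (pid in unique(patient)) {
    rows <- patient == pid
    xi <- x[rows]; yi <- y[rows]
    u <- seq(-8 * sigma_u, 8 * sigma_u, length.out = n_grid)
    h <- vapply(u, function(ui) {
      eta <- alpha + beta * xi + ui
      sum(yi * eta - log1p(exp(eta))) + dnorm(ui, 0, sigma_u, log = TRUE)
    }, numeric(1))
    mx <- max(h)
    du <- u[2] - u[1]
    total <- total + mx + log(sum(exp(h - mx)) * du)
  }
  total
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exact null distribution of the mean within-patient Spearman rho for a list
# of per-patient (x, y) series, enumerating the joint covariate permutations.
enumerate_mean_rho <- function(series) {
  perm_sets <- lapply(series, function(d) all_perms(length(d$y)))
  grid <- expand.grid(lapply(perm_sets, seq_along))
  vapply(seq_len(nrow(grid)), function(r) {
    rhos <- vapply(seq_along(series), function(i) {
      d <- series[[i]]
      perm <- perm_sets[[i]][[grid[r, i]]]
      cor(rank(d$x), rank(d$y[perm]))
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
}

# Closed-form one-way ANOVA from sums of squares.
anova_by_hand <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups)); n <- length(values)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Normal-equations simple linear regression with the t test of the slope.
ols_by_hand <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, t = t, p = 2 * pt(-abs(t), n - 2))
}

# Minimal valid two-patient cohort builder for hand-constructed cases.
mini_cohort <- function(visits_overrides = list(), n_months = 3) {
  patients <- data.frame(
    patient_id = c("A", "B"),
    gender = c("male", "female"),
    age_at_study_start = c(10, 12),
    age_at_transplant = c(5, 8),
    post_transplant_time = c(5, 4),
    primary_disease = c("CAKUT", "cystic"),
    donation_type = c("living", "deceased"),
    hla_mismatch = c(2L, 3L),
    dsa_positive = c(FALSE, TRUE),
    cni_or_mtori = c("tacrolimus", "tacrolimus"),
    antiproliferative = c("MMF", "none"),
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    patient_id = rep(c("A", "B"), each = n_months),
    month_index = rep(seq_len(n_months) - 1L, 2),
    ttv_raw = 10^runif(2 * n_months, 3, 7),
    prednisolone_dose = runif(2 * n_months, 2, 8),
    tacrolimus_dose = 0.15,
    cyclosporin_dose = NA_real_, rapamycin_dose = NA_real_,
    mmf_dose = rep(c(1100, NA), each = n_months),
    azathioprine_dose = NA_real_,
    tacrolimus_trough = 6,
    cyclosporin_trough = NA_real_, rapamycin_trough = NA_real_,
    egfr = 75, ebv_log10 = 0, cmv_log10 = 0, bkv_log10 = 0,
    infection = FALSE, febrile_infection = FALSE,
    nonadherence_suspected = FALSE,
    stringsAsFactors = FALSE
  )
  for (nm in names(visits_overrides)) visits[[nm]] <- visits_overrides[[nm]]
  new_cohort(patients, visits)
}
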