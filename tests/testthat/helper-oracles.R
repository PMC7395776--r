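# Independent oracles used across test files. Each is a deliberately
# simple-minded reimplementation (brute force, enumeration, closed form or
# direct simulation) kept free of the package's own computational paths.

# AUC by exhaustive case-control pair enumeration within strata.
brute_auc <- function(scores, status, stratum = rep(1L, length(scores))) {
  num <- den <- 0
  for (s in unique(stratum)) {
    cases <- scores[stratum == s & status == 1]
    controls <- scores[stratum == s & status == 0]
    for (x in cases) for (y in controls) {
      num <- num + (x > y) + 0.5 * (x == y)
      den <- den + 1
    }
  }
  num / den
}

# Unadjusted log OR and Wald SE from a 2x2 collapse.
brute_2x2 <- function(exposed_cases, unexposed_cases,
                      exposed_controls, unexposed_controls) {
  or <- (exposed_cases * unexposed_controls) /
    (unexposed_cases * exposed_controls)
  se <- sqrt(1 / exposed_cases + 1 / unexposed_cases +
               1 / exposed_controls + 1 / unexposed_controls)
  list(log_or = log(or), se = se)
}

# Elementwise-sum PRS, including orientation flips, without matrix algebra.
brute_prs <- function(dosages, panel, weight_col = "weight_overall") {
  info <- attr(dosages, "variant_info")
  n <- nrow(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nrow(panel))) {
      j <- match(panel$variant_id[k], info$variant_id)
      x <- unclass(dosages)[i, j]
      if (info$counted_allele[j] == panel$other_allele[k]) x <- 2 - x
      acc <- acc + panel[[weight_col]][k] * x
    }
    out[i] <- acc
  }
  out
}

# Monte-Carlo percentile-bin odds ratios under the logistic model:
# simulate PRS z ~ N(0,1), disease with P = expit(b0 + gamma z) at the
# stated prevalence, bin on control quantiles, and tabulate bin-vs-reference
# odds ratios directly.
mc_bin_or <- function(gamma, scheme, prevalence = 0.01, n = 2e6, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  b0 <- uniroot(function(b) mean(plogis(b + gamma * z)) - prevalence,
                c(-30, 10), tol = 1e-10)$root
  status <- rbinom(n, 1L, plogis(b0 + gamma * z))
  inner <- scheme$boundaries[-c(1, length(scheme$boundaries))]
  cuts <- quantile(z[status == 0], probs = inner, type = 7, names = FALSE)
  bin <- findInterval(z, cuts) + 1L
  tab <- table(factor(bin, levels = seq_along(scheme$labels)), status)
  ref <- scheme$reference
  odds <- tab[, "1"] / tab[, "0"]
  or <- as.numeric(odds / odds[ref])
  se <- sqrt(1 / tab[, "1"] + 1 / tab[, "0"] +
               1 / tab[ref, "1"] + 1 / tab[ref, "0"])
  list(or = or, se_log = as.numeric(se))
}

# Profiled marginal-likelihood variance-components oracle for the
# hierarchical measurement-error model: y_ij ~ N(alpha_i, s + se_ij^2) with
# alpha_i profiled out at each candidate s; s maximises the marginal
# likelihood numerically.
ml_icc_oracle <- function(y, se) {
  v <- se^2
  prof_alpha <- function(s) {
    w <- 1 / (s + v)
    rowSums(y * w, na.rm = TRUE) / rowSums(w * !is.na(y), na.rm = TRUE)
  }
  negll <- function(s) {
    a <- prof_alpha(s)
    tot <- s + v
    sum(0.5 * log(tot) + 0.5 * (y - a)^2 / tot, na.rm = TRUE)
  }
  upper <- max(10 * var(as.vector(y), na.rm = TRUE), 1e-4)
  s_hat <- optimize(negll, c(0, upper))$minimum
  a <- prof_alpha(s_hat)
  list(sigma2_R = s_hat, alpha = a, icc = var(a) / (var(a) + s_hat))
}

# Life-history microsimulation for screening eligibility: each woman draws
# a PRS centile, lives through the calibrated hazards year by year, and may
# die of competing causes; returns the fraction of cases arising in
# eligible centiles.
micro_cases_captured <- function(curve, eligible, n = 2e5, seed = 1) {
  set.seed(seed)
  groups <- curve$groups
  g <- sample.int(nrow(groups), n, replace = TRUE, prob = groups$fraction)
  case_in_eligible <- 0
  cases <- 0
  n_age <- length(curve$ages)
  alive <- rep(TRUE, n)
  for (u in seq_len(n_age)) {
    lam <- curve$lambda[u, g]
    mort <- 1 - curve$S_m[min(u + 1, n_age)] / curve$S_m[u]
    event <- alive & (runif(n) < lam)
    cases <- cases + sum(event)
    case_in_eligible <- case_in_eligible + sum(event & eligible[g])
    alive <- alive & !event & (runif(n) >= mort)
  }
  case_in_eligible / cases
}

# Cohort generation + standardisation shorthand used across files.
make_scored_cohort <- function(cfg, with_fh = FALSE) {
  cc <- gen_case_control_cohort(gen_weight_panel(cfg), cfg)
  cohort <- cc$cohort
  if (with_fh) cohort <- gen_family_history(cohort, cfg)
  cohort$prs <- standardize_prs(cohort$prs_raw,
                                cfg$control_sd_pop1)$standardized_value
  list(cohort = cohort, truth = cc$truth)
}
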