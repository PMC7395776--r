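# Association statistics: per-SD and percentile-bin odds ratios, prospective
# hazard ratios, study-adjusted AUC, fixed-effect meta-analysis, interaction
# tests and family-history attenuation. Fits go through stats::glm /
# survival::coxph; this file owns the study-specific conventions (control
# quantile bins, within-stratum AUC pooling, log-scale attenuation).

estimate_ci <- function(log_est, se, scale = "log-odds",
                        n_cases = NA_integer_, n_controls = NA_integer_,
                        p = NULL) {
  z <- stats::qnorm(0.975)
  structure(list(
    estimate = log_est, se = se,
    point = exp(log_est), lcl = exp(log_est - z * se),
    ucl = exp(log_est + z * se),
    p = if (is.null(p)) 2 * stats::pnorm(-abs(log_est / se)) else p,
    scale = scale, n_cases = n_cases, n_controls = n_controls
  ), class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, ...) {
  lab <- if (x$scale == "log-hazard") "HR" else "OR"
  cat(sprintf("%s %.3f (95%% CI %.3f-%.3f), p = %.3g [%s scale]\n",
              lab, x$point, x$lcl, x$ucl, x$p, x$scale))
  invisible(x)
}

.default_covariates <- function(cohort) {
  cand <- c(paste0("pc", 1:10), "stratum")
  cand[cand %in% names(cohort) &
         vapply(cand, function(v) v %in% names(cohort) &&
                  length(unique(cohort[[v]])) > 1L, logical(1))]
}

.build_formula <- function(response, terms) {
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Per-SD odds ratio from covariate-adjusted logistic regression
#'
#' Fits \code{status ~ prs + covariates} by maximum likelihood and reports
#' the Wald odds ratio per unit of the (standardised) PRS with a 95\% CI.
#' Default covariates are the first ten principal components and stratum
#' indicators, when present in the cohort.
#'
#' @param cohort cohort data frame with a binary \code{status} column.
#' @param prs_col name of the PRS column (standardised scores).
#' @param covariates character vector of covariate column names.
#' @return an \code{estimate_ci} (log-odds scale internally, OR reported).
#' @export
fit_logistic_per_sd <- function(cohort, prs_col = "prs",
                                covariates = .default_covariates(cohort)) {
  stopifnot(prs_col %in% names(cohort), "status" %in% names(cohort))
  if (length(unique(cohort$status)) != 2L)
    stop("both outcome classes must be present")
  fit <- stats::glm(.build_formula("status", c(prs_col, covariates)),
                    family = stats::binomial(), data = cohort,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation); deviance = ",
         format(fit$deviance))
  cf <- summary(fit)$coefficients
  if (!prs_col %in% rownames(cf)) stop("rank-deficient design: PRS aliased")
  estimate_ci(cf[prs_col, 1], cf[prs_col, 2], "log-odds",
              n_cases = sum(cohort$status == 1),
              n_controls = sum(cohort$status == 0))
}

#' Percentile-bin scheme on the control PRS distribution
#'
#' Cumulative control-fraction cut points defining PRS percentile ranges;
#' the default is the 11-bin scheme <1, 1-5, 5-10, 10-20, 20-40, 40-60
#' (reference), 60-80, 80-90, 90-95, 95-99, >99\%.
#'
#' @param boundaries strictly increasing cut points from 0 to 1.
#' @param reference index of the reference bin.
#' @return classed list with \code{boundaries}, \code{reference},
#'   \code{labels}.
#' @export
bin_scheme <- function(boundaries = c(0, .01, .05, .10, .20, .40, .60,
                                      .80, .90, .95, .99, 1),
                       reference = which(boundaries == .40)) {
  stopifnot(all(diff(boundaries) > 0), boundaries[1] == 0,
            boundaries[length(boundaries)] == 1,
            length(reference) == 1L, reference >= 1,
            reference <= length(boundaries) - 1L)
  labels <- paste0(100 * boundaries[-length(boundaries)], "-",
                   100 * boundaries[-1], "%")
  structure(list(boundaries = boundaries, reference = as.integer(reference),
                 labels = labels),
            class = "bin_scheme")
}

# bin membership: control-distribution quantiles (type 7), boundary values
# go to the upper bin
.assign_bins <- function(prs, status, scheme) {
  inner <- scheme$boundaries[-c(1, length(scheme$boundaries))]
  cuts <- stats::quantile(prs[status == 0], probs = inner, type = 7,
                          names = FALSE)
  findInterval(prs, cuts) + 1L
}

#' Odds ratios by PRS percentile bin
#'
#' Bin membership is defined by control-distribution quantiles at the
#' scheme's cut points and applied to cases and controls alike; a logistic
#' model with bin indicators (reference bin = 40-60\% by default) and the
#' given covariates yields one OR per bin, identically 1 for the reference.
#'
#' @inheritParams fit_logistic_per_sd
#' @param scheme a [bin_scheme()].
#' @return data frame with one row per bin: label, boundaries, counts, OR
#'   with CI (reference row has OR 1 and NA CI).
#' @export
percentile_bin_or <- function(cohort, prs_col = "prs",
                              scheme = bin_scheme(),
                              covariates = .default_covariates(cohort)) {
  stopifnot(prs_col %in% names(cohort))
  bins <- .assign_bins(cohort[[prs_col]], cohort$status, scheme)
  n_bins <- length(scheme$labels)
  tab <- table(factor(bins, levels = seq_len(n_bins)), cohort$status)
  if (any(tab == 0)) stop("empty bin: every bin needs cases and controls")
  f <- stats::relevel(factor(bins, levels = seq_len(n_bins),
                             labels = scheme$labels),
                      ref = scheme$labels[scheme$reference])
  dat <- cohort
  dat$.bin <- f
  fit <- stats::glm(.build_formula("status", c(".bin", covariates)),
                    family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  out <- data.frame(
    bin = scheme$labels,
    lower = scheme$boundaries[-(n_bins + 1)],
    upper = scheme$boundaries[-1],
    n_cases = as.integer(tab[, "1"]),
    n_controls = as.integer(tab[, "0"]),
    or = NA_real_, lcl = NA_real_, ucl = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_bins)) {
    if (i == scheme$reference) {
      out$or[i] <- 1
    } else {
      rn <- paste0(".bin", scheme$labels[i])
      out$or[i] <- exp(cf[rn, 1])
      out$lcl[i] <- exp(cf[rn, 1] - z * cf[rn, 2])
      out$ucl[i] <- exp(cf[rn, 1] + z * cf[rn, 2])
    }
  }
  out
}

#' Per-SD hazard ratio from a Cox model with delayed entry
#'
#' Age is the time scale (entry at cohort entry age, exit at diagnosis or
#' censoring); ties are handled by the Efron approximation.
#'
#' @param cohort prospective cohort with \code{entry_age}, \code{exit_age},
#'   \code{event} and the PRS column.
#' @param prs_col name of the (standardised) PRS column.
#' @param covariates covariate column names (default: pc1..pc7 if present).
#' @return an \code{estimate_ci} on the log-hazard scale.
#' @export
fit_cox_per_sd <- function(cohort, prs_col = "prs",
                           covariates = intersect(paste0("pc", 1:7),
                                                  names(cohort))) {
  stopifnot(all(c("entry_age", "exit_age", "event") %in% names(cohort)))
  if (sum(cohort$event) < 1) stop("no events in cohort")
  if (any(cohort$exit_age <= cohort$entry_age))
    stop("exit_age must exceed entry_age")
  fml <- .build_formula("survival::Surv(entry_age, exit_age, event)",
                        c(prs_col, covariates))
  fit <- survival::coxph(fml, data = cohort, ties = "efron")
  cf <- summary(fit)$coefficients
  estimate_ci(cf[prs_col, "coef"], cf[prs_col, "se(coef)"], "log-hazard",
              n_cases = sum(cohort$event),
              n_controls = nrow(cohort) - sum(cohort$event))
}

#' Study-adjusted AUC
#'
#' Concordance restricted to within-stratum case-control pairs: for each
#' stratum with at least one case and one control, the probability that a
#' random case outscores a random control (ties counting 1/2), pooled
#' across strata with weights proportional to the number of case-control
#' pairs.
#'
#' @param scores numeric risk scores.
#' @param status binary outcome.
#' @param stratum stratum labels (a single label gives the unadjusted AUC).
#' @return pooled AUC in \[0,1\].
#' @export
study_adjusted_auc <- function(scores, status,
                               stratum = rep(1L, length(scores))) {
  stopifnot(length(scores) == length(status),
            length(stratum) == length(scores))
  total_pairs <- 0
  weighted <- 0
  for (s in unique(stratum)) {
    sel <- stratum == s
    x <- scores[sel & status == 1]
    y <- scores[sel & status == 0]
    if (length(x) == 0 || length(y) == 0) next
    r <- rank(c(x, y))
    # Mann-Whitney with midranks: ties count 1/2
    nx <- as.numeric(length(x))
    ny <- as.numeric(length(y))
    auc_s <- (sum(r[seq_along(x)]) - nx * (nx + 1) / 2) / (nx * ny)
    w <- nx * ny
    weighted <- weighted + w * auc_s
    total_pairs <- total_pairs + w
  }
  if (total_pairs == 0) stop("no stratum contains both a case and a control")
  weighted / total_pairs
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools log-scale estimates with weights \eqn{w_i = 1/se_i^2}. Cochran's
#' \eqn{Q = \sum w_i (b_i - \bar b)^2} with \eqn{df = k - 1},
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} and a chi-square
#' heterogeneity p value. Input is either a data frame with columns
#' \code{estimate} and \code{se} (log scale) or columns \code{or},
#' \code{lcl}, \code{ucl} (ratio scale, SE recovered from the CI width), or
#' a list of \code{estimate_ci} objects.
#'
#' @param estimates per-study estimates (see above).
#' @return list with \code{pooled} (an \code{estimate_ci}), \code{Q},
#'   \code{df}, \code{I2} (percent), \code{p_het}, \code{k}.
#' @export
fixed_effect_meta <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "estimate_ci"))) {
    b <- vapply(estimates, `[[`, numeric(1), "estimate")
    se <- vapply(estimates, `[[`, numeric(1), "se")
  } else {
    estimates <- as.data.frame(estimates)
    if (all(c("estimate", "se") %in% names(estimates))) {
      b <- estimates$estimate
      se <- estimates$se
    } else if (all(c("or", "lcl", "ucl") %in% names(estimates))) {
      b <- log(estimates$or)
      se <- (log(estimates$ucl) - log(estimates$lcl)) /
        (2 * stats::qnorm(0.975))
    } else stop("estimates must carry (estimate, se) or (or, lcl, ucl)")
  }
  if (length(b) < 1) stop("need at least one estimate")
  if (any(se <= 0)) stop("zero-width confidence interval (se <= 0)")
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  Q <- sum(w * (b - pooled)^2)
  df <- length(b) - 1L
  I2 <- if (df == 0 || Q <= 0) 0 else max(0, (Q - df) / Q) * 100
  p_het <- if (df == 0) NA_real_ else stats::pchisq(Q, df, lower.tail = FALSE)
  list(pooled = estimate_ci(pooled, sqrt(1 / sum(w))),
       Q = Q, df = df, I2 = I2, p_het = p_het, k = length(b))
}

#' Test effect modification of the PRS by a covariate
#'
#' Adds a product term \code{prs x modifier} to the adjusted logistic model
#' and reports the interaction coefficient with a Wald z test (the
#' asymptotic equivalent of the t test sometimes quoted for interaction
#' terms).
#'
#' @inheritParams fit_logistic_per_sd
#' @param modifier name of the modifying covariate (e.g. \code{"age"},
#'   \code{"family_history"}).
#' @return an \code{estimate_ci} for the interaction term (ratio of ORs).
#' @export
interaction_test <- function(cohort, modifier, prs_col = "prs",
                             covariates = .default_covariates(cohort)) {
  stopifnot(modifier %in% names(cohort))
  if (length(unique(cohort[[modifier]])) < 2L)
    stop("modifier is constant")
  terms <- c(prs_col, modifier, paste0(prs_col, ":", modifier),
             setdiff(covariates, modifier))
  fit <- stats::glm(.build_formula("status", terms),
                    family = stats::binomial(), data = cohort,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient interaction model: modifier collinear with the ",
         "PRS or covariates")
  cf <- summary(fit)$coefficients
  rn <- grep(":", rownames(cf), value = TRUE)
  if (length(rn) != 1L) stop("interaction term aliased")
  estimate_ci(cf[rn, 1], cf[rn, 2], "log-odds",
              n_cases = sum(cohort$status == 1),
              n_controls = sum(cohort$status == 0))
}

#' Log-scale attenuation between two odds ratios
#'
#' \eqn{100 (\ln OR_{unadj} - \ln OR_{adj}) / \ln OR_{unadj}}: the
#' percentage of the unadjusted log odds ratio removed by the adjustment.
#' Undefined (NA, with a warning) when the unadjusted OR is at or below 1.
#'
#' @param or_unadj,or_adj positive odds ratios.
#' @return attenuation percentage.
#' @export
log_attenuation <- function(or_unadj, or_adj) {
  stopifnot(or_unadj > 0, or_adj > 0)
  if (or_unadj <= 1) {
    warning("attenuation undefined for unadjusted OR <= 1")
    return(NA_real_)
  }
  100 * (log(or_unadj) - log(or_adj)) / log(or_unadj)
}

#' Family-history association before and after PRS adjustment
#'
#' Fits the family-history odds ratio adjusted for the standard covariates,
#' then refits additionally conditioning on the PRS, and reports the
#' log-scale attenuation. Rows with missing family history are excluded.
#'
#' @inheritParams fit_logistic_per_sd
#' @return list with \code{or_unadjusted}, \code{or_adjusted} (both
#'   \code{estimate_ci}) and \code{attenuation_pct}.
#' @export
fh_attenuation <- function(cohort, prs_col = "prs",
                           covariates = .default_covariates(cohort)) {
  stopifnot("family_history" %in% names(cohort))
  dat <- cohort[!is.na(cohort$family_history), , drop = FALSE]
  if (!nrow(dat)) stop("no rows with non-missing family history")
  fit1 <- stats::glm(.build_formula("status", c("family_history", covariates)),
                     family = stats::binomial(), data = dat)
  fit2 <- stats::glm(.build_formula("status",
                                    c("family_history", prs_col, covariates)),
                     family = stats::binomial(), data = dat)
  cf1 <- summary(fit1)$coefficients["family_history", ]
  cf2 <- summary(fit2)$coefficients["family_history", ]
  e1 <- estimate_ci(cf1[1], cf1[2], "log-odds",
                    n_cases = sum(dat$status == 1),
                    n_controls = sum(dat$status == 0))
  e2 <- estimate_ci(cf2[1], cf2[2], "log-odds",
                    n_cases = sum(dat$status == 1),
                    n_controls = sum(dat$status == 0))
  list(or_unadjusted = e1, or_adjusted = e2,
       attenuation_pct = log_attenuation(e1$point, e2$point))
}

#' Rescale an odds ratio between SD conventions
#'
#' An OR per SD depends on which population's control SD standardises the
#' PRS; moving from a reference SD \code{sd_from} to a target SD
#' \code{sd_to} rescales the log OR by \code{sd_to / sd_from}.
#'
#' @param or_value positive odds ratio per \code{sd_from} unit.
#' @param sd_from,sd_to positive standard deviations.
#' @return the odds ratio per \code{sd_to} unit.
#' @export
rescale_or <- function(or_value, sd_from, sd_to) {
  stopifnot(or_value > 0, sd_from > 0, sd_to > 0)
  exp(log(or_value) * sd_to / sd_from)
}
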