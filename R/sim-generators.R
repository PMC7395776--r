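# Synthetic-data generators. Every generator is a pure function of
# (inputs, config); the config seed fully determines the output, so a rerun
# with the same config is byte-identical. Ground-truth parameters are
# attached so downstream estimators can be checked for recovery.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# Intercept b0 such that E[expit(b0 + beta * X)] = target for X ~ N(mu, sd).
.solve_intercept <- function(beta, mu, sd, target) {
  marginal <- function(b0) {
    stats::integrate(function(z) stats::dnorm(z) * expit(b0 + beta * (mu + sd * z)),
                     -8, 8)$value - target
  }
  stats::uniroot(marginal, c(logit(target) - abs(beta) * sd * 8 - 2,
                             logit(target) + abs(beta) * sd * 8 + 2),
                 tol = 1e-10)$root
}

#' Generate a synthetic SNP weight panel
#'
#' Draws a panel of independent SNPs with per-allele log-odds weights scaled
#' so that the implied population-1 PRS standard deviation (under
#' binomial(2, freq) dosages) equals \code{control_sd_pop1}. A configurable
#' fraction of SNPs is common in population 1 but rare (MAF < 0.05) in
#' population 2, which lowers the implied population-2 SD the way a
#' European-derived panel loses variance in Asian carriers. Subtype weight
#' columns are proportional rescalings of the overall weights. A configurable
#' number of SNPs receives an imputation INFO score below 0.9.
#'
#' @param config a [sim_config()].
#' @return A [weight_panel()] with attribute \code{true_sd}, the panel-implied
#'   PRS standard deviations per population.
#' @export
gen_weight_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_snps
  if (n < 1L) stop("n_snps must be >= 1")

  freq_pop1 <- stats::runif(n, 0.10, 0.50)
  rare <- stats::runif(n) < config$frac_rare_pop2
  freq_pop2 <- ifelse(rare, stats::runif(n, 0.005, 0.045),
                      stats::runif(n, 0.10, 0.50))

  alleles <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2),
                      character(2)))

  w <- stats::rnorm(n)
  v1 <- 2 * freq_pop1 * (1 - freq_pop1)
  w <- w * config$control_sd_pop1 / sqrt(sum(w^2 * v1))
  sd_pop2 <- sqrt(sum(w^2 * 2 * freq_pop2 * (1 - freq_pop2)))

  info <- stats::runif(n, 0.90, 1.00)
  if (config$n_low_info > 0L) {
    low <- sample.int(n, config$n_low_info)
    info[low] <- stats::runif(config$n_low_info, 0.50, 0.899)
  }

  panel <- weight_panel(data.frame(
    variant_id = sprintf("rs%07d", sample.int(9999999L, n)),
    chr = sample(1:22, n, replace = TRUE),
    pos = sample.int(2.4e8, n),
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    weight_overall = w,
    weight_erpos = w * (0.638 / 0.597),
    weight_erneg = w * (0.567 / 0.597),
    info = info,
    freq_pop1 = freq_pop1,
    freq_pop2 = freq_pop2,
    stringsAsFactors = FALSE
  ))
  attr(panel, "true_sd") <- c(pop1 = config$control_sd_pop1, pop2 = sd_pop2)
  panel
}

.panel_moments <- function(panel, population, weight_set = "overall") {
  p <- panel[[paste0("freq_", population)]]
  w <- panel[[paste0("weight_", weight_set)]]
  c(mean = sum(w * 2 * p), sd = sqrt(sum(w^2 * 2 * p * (1 - p))))
}

#' Generate a synthetic case-control cohort
#'
#' Samples case status under a log-linear (logistic) model in the raw PRS at
#' a configurable baseline prevalence, by rejection from a finite synthetic
#' population, until exactly \code{n_cases} cases and \code{n_controls}
#' controls are collected. By default individual PRSs are drawn from the
#' normal approximation at the configured population-2 mean and SD (the
#' limit the independent-SNP dosage model converges to); with
#' \code{include_dosages = TRUE} per-SNP binomial(2, freq) dosages are drawn
#' and scored through the panel instead, and the dosage matrix of the
#' retained individuals is returned.
#'
#' Strata, ten null principal-component covariates, age, and ER subtype
#' labels for cases are attached. The per-raw-unit log odds ratio is
#' \code{per_sd_log_or / control_sd_pop1}, i.e. the configured effect is per
#' reference-control SD.
#'
#' @param panel a [weight_panel()].
#' @param config a [sim_config()].
#' @param include_dosages draw and return per-SNP dosages (slower).
#' @param population which frequency column drives dosages/PRS moments.
#' @return A list with elements \code{cohort} (data frame), \code{dosages}
#'   (a [dosage_matrix()] or NULL), and \code{truth} (ground-truth list).
#' @export
gen_case_control_cohort <- function(panel, config, include_dosages = FALSE,
                                    population = "pop2") {
  validate_sim_config(config)
  stopifnot(nrow(panel) >= 1L)
  set.seed(config$seed + 1L)

  beta_raw <- config$per_sd_log_or / config$control_sd_pop1
  if (include_dosages) {
    mom <- .panel_moments(panel, population)
    mu <- mom["mean"]; sdv <- mom["sd"]
  } else {
    mu <- config$prs_mean_pop2; sdv <- config$control_sd_pop2
  }
  b0 <- .solve_intercept(beta_raw, mu, sdv, config$prevalence)

  need_cases <- config$n_cases
  need_controls <- config$n_controls
  # expected draws needed, with head-room; hard cap guards impossible asks
  exp_n <- max(need_cases / config$prevalence,
               need_controls / (1 - config$prevalence))
  max_draws <- ceiling(exp_n * 3) + 1e4
  chunk <- min(2e5, max_draws)

  acc_prs <- list(case = numeric(0), control = numeric(0))
  acc_dos <- list(case = NULL, control = NULL)
  drawn <- 0
  while ((length(acc_prs$case) < need_cases ||
          length(acc_prs$control) < need_controls) && drawn < max_draws) {
    m <- min(chunk, max_draws - drawn)
    drawn <- drawn + m
    if (include_dosages) {
      p <- panel[[paste0("freq_", population)]]
      X <- matrix(stats::rbinom(m * nrow(panel), 2L, rep(p, each = m)),
                  nrow = m)
      prs <- as.numeric(X %*% panel$weight_overall)
    } else {
      prs <- stats::rnorm(m, mu, sdv)
    }
    status <- stats::rbinom(m, 1L, expit(b0 + beta_raw * prs))
    for (grp in c("case", "control")) {
      sel <- if (grp == "case") status == 1L else status == 0L
      need <- if (grp == "case") need_cases else need_controls
      take <- min(sum(sel), need - length(acc_prs[[grp]]))
      if (take > 0) {
        idx <- which(sel)[seq_len(take)]
        acc_prs[[grp]] <- c(acc_prs[[grp]], prs[idx])
        if (include_dosages)
          acc_dos[[grp]] <- rbind(acc_dos[[grp]], X[idx, , drop = FALSE])
      }
    }
  }
  if (length(acc_prs$case) < need_cases ||
      length(acc_prs$control) < need_controls)
    stop("unattainable case/control count at prevalence ", config$prevalence,
         " within ", max_draws, " draws")

  n <- need_cases + need_controls
  status <- rep(c(1L, 0L), c(need_cases, need_controls))
  prs_raw <- c(acc_prs$case, acc_prs$control)

  er <- rep("unknown", n)
  u <- stats::runif(need_cases)
  er[seq_len(need_cases)] <- ifelse(
    u < config$er_pos_frac, "positive",
    ifelse(u < config$er_pos_frac + config$er_neg_frac, "negative", "unknown"))

  cohort <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    status = status,
    er_status = er,
    age = pmin(pmax(round(stats::rnorm(n, 52, 10)), 25), 80),
    ethnicity = population,
    stratum = paste0("study", sample.int(config$n_strata, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  cohort <- cbind(cohort, pcs)
  cohort$family_history <- NA_integer_
  cohort$prs_raw <- prs_raw

  dos <- NULL
  if (include_dosages) {
    dos <- dosage_matrix(
      rbind(acc_dos$case, acc_dos$control),
      variant_info = data.frame(
        variant_id = panel$variant_id,
        counted_allele = panel$effect_allele,
        other_allele = panel$other_allele,
        stringsAsFactors = FALSE),
      sample_ids = cohort$sample_id)
  }

  truth <- list(
    true_gamma = config$per_sd_log_or,
    true_beta_raw = beta_raw,
    true_prs_sd_by_pop = c(pop1 = config$control_sd_pop1, pop2 = unname(sdv)),
    prevalence = config$prevalence,
    seed = config$seed
  )
  list(cohort = cohort, dosages = dos, truth = truth)
}

#' Attach a simulated first-degree family history
#'
#' Simulates one first-degree relative per woman whose PRS correlates with
#' the index woman's at \code{fh_relative_correlation}, and whose lifetime
#' disease status follows the same log-linear model, calibrated so the
#' population-marginal family-history prevalence equals
#' \code{fh_prevalence}. Because relatives of high-PRS women have high PRS
#' themselves, family history is positively associated with case status
#' whenever the PRS effect is non-zero, and adjusting for the index PRS
#' attenuates that association.
#'
#' @param cohort a cohort data frame carrying \code{prs_raw}.
#' @param config a [sim_config()].
#' @return The cohort with its \code{family_history} column filled in.
#' @export
gen_family_history <- function(cohort, config) {
  validate_sim_config(config)
  if (is.null(cohort$prs_raw)) stop("cohort must carry a prs_raw column")
  rho <- config$fh_relative_correlation
  if (rho < 0 || rho > 1) stop("fh_relative_correlation outside [0,1]")
  set.seed(config$seed + 2L)

  mu <- config$prs_mean_pop2; sdv <- config$control_sd_pop2
  beta_raw <- config$per_sd_log_or / config$control_sd_pop1
  rel_prs <- mu + rho * (cohort$prs_raw - mu) +
    sqrt(1 - rho^2) * sdv * stats::rnorm(nrow(cohort))
  b0 <- .solve_intercept(beta_raw, mu, sdv, config$fh_prevalence)
  cohort$family_history <- stats::rbinom(nrow(cohort), 1L,
                                         expit(b0 + beta_raw * rel_prs))
  cohort
}

#' Generate a right-censored prospective cohort
#'
#' Event times are exponential with per-woman hazard
#' \code{lambda0 * exp(beta_raw * (PRS - mean PRS))}, where \code{lambda0}
#' is set so the marginal event rate matches \code{config$event_rate}
#' (events per person-year). Censoring is the earlier of administrative
#' follow-up end and an independent exponential censoring time.
#'
#' @param panel a [weight_panel()] (used for PRS moments when
#'   \code{include_dosages = TRUE}; otherwise moments come from the config).
#' @param config a [sim_config()].
#' @param include_dosages draw per-SNP dosages rather than normal PRSs.
#' @return list with \code{cohort} (entry/exit age, event flag, PRS, PCs)
#'   and \code{truth}.
#' @export
gen_prospective_cohort <- function(panel, config, include_dosages = FALSE) {
  validate_sim_config(config)
  if (config$followup_years <= 0) stop("followup_years must be positive")
  if (config$censoring_rate < 0) stop("censoring_rate must be non-negative")
  set.seed(config$seed + 3L)

  n <- config$n_women
  beta_raw <- config$per_sd_log_or / config$control_sd_pop1
  if (include_dosages) {
    p <- panel$freq_pop2
    X <- matrix(stats::rbinom(n * nrow(panel), 2L, rep(p, each = n)), nrow = n)
    prs <- as.numeric(X %*% panel$weight_overall)
    mom <- .panel_moments(panel, "pop2")
    mu <- mom["mean"]; sdv <- mom["sd"]
  } else {
    mu <- config$prs_mean_pop2; sdv <- config$control_sd_pop2
    prs <- stats::rnorm(n, mu, sdv)
  }
  # E[exp(beta (X - mu))] for X ~ N(mu, sd): exp(beta^2 sd^2 / 2)
  lambda0 <- config$event_rate / exp(beta_raw^2 * sdv^2 / 2)
  hazard <- lambda0 * exp(beta_raw * (prs - mu))

  entry <- stats::runif(n, config$entry_age_range[1], config$entry_age_range[2])
  t_event <- stats::rexp(n, hazard)
  t_cens <- if (config$censoring_rate > 0)
    stats::rexp(n, config$censoring_rate) else rep(Inf, n)
  t_obs <- pmin(t_event, t_cens, config$followup_years)
  event <- as.integer(t_event <= pmin(t_cens, config$followup_years))

  pcs <- matrix(stats::rnorm(n * 7), n, 7,
                dimnames = list(NULL, paste0("pc", 1:7)))
  cohort <- data.frame(
    sample_id = sprintf("P%06d", seq_len(n)),
    entry_age = entry,
    exit_age = entry + t_obs,
    event = event,
    prs_raw = prs,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, pcs)

  truth <- list(true_gamma = config$per_sd_log_or,
                true_beta_raw = beta_raw,
                lambda0 = lambda0, seed = config$seed)
  list(cohort = cohort, truth = truth)
}

#' Generate a synthetic age-specific rates table
#'
#' Stand-in for registry incidence and competing (non-breast-cancer)
#' mortality tables. The default shape places the incidence peak between
#' ages 40 and 55 (as in East/Southeast Asian registries) with Gompertz
#' competing mortality.
#'
#' @param ages integer age grid (contiguous).
#' @param shape \code{"peaked"} (Gaussian-in-age incidence bump) or
#'   \code{"constant"}.
#' @param peak_rate incidence per person-year at the peak age.
#' @param peak_age,width location and spread of the incidence peak.
#' @param mort0 competing mortality per person-year at the first age.
#' @param mort_doubling years over which competing mortality doubles.
#' @return a [rates_table()].
#' @export
gen_rates_table <- function(ages = 20:89, shape = c("peaked", "constant"),
                            peak_rate = 0.002, peak_age = 50, width = 15,
                            mort0 = 5e-5, mort_doubling = 8) {
  shape <- match.arg(shape)
  if (any(diff(ages) != 1L)) stop("age grid must be contiguous")
  inc <- switch(shape,
    peaked = peak_rate * exp(-0.5 * ((ages - peak_age) / width)^2),
    constant = rep(peak_rate, length(ages)))
  mort <- mort0 * 2^((ages - ages[1]) / mort_doubling)
  rates_table(age = ages, incidence = inc, competing_mortality = mort)
}

#' Generate a synthetic panel of per-SNP effect estimates across populations
#'
#' Simulates the two-level structure of cross-population per-SNP effect
#' sizes: a shared per-SNP mean effect \code{alpha_i} with between-SNP
#' standard deviation \code{between_sd}, population-specific true effects
#' deviating with standard deviation \code{within_sd}, and observed
#' estimates equal to the true effects plus sampling noise with known
#' standard errors drawn uniformly from \code{se_range}. The generated
#' ground-truth intraclass correlation is
#' \code{between_sd^2 / (between_sd^2 + within_sd^2)}.
#'
#' @param n_snps number of SNPs.
#' @param populations character vector of population labels.
#' @param between_sd SD of shared per-SNP mean effects.
#' @param within_sd SD of population-specific deviations (0 = fully shared
#'   architecture).
#' @param se_range range of per-estimate standard errors.
#' @param mean_effect mean of the shared effects.
#' @param seed integer seed.
#' @return list with \code{panel} (an [effect_panel()]) and \code{truth}
#'   (including \code{true_icc}).
#' @export
gen_effect_panel <- function(n_snps = 100L, populations = c("pop1", "pop2"),
                             between_sd = 0.06, within_sd = 0,
                             se_range = c(0.02, 0.08), mean_effect = 0.05,
                             seed = 1L) {
  stopifnot(n_snps >= 3L, length(populations) >= 2L,
            between_sd >= 0, within_sd >= 0)
  set.seed(as.integer(seed))
  m <- length(populations)
  alpha <- stats::rnorm(n_snps, mean_effect, between_sd)
  beta <- alpha + matrix(stats::rnorm(n_snps * m, 0, within_sd), n_snps, m)
  se <- matrix(stats::runif(n_snps * m, se_range[1], se_range[2]), n_snps, m)
  y <- beta + matrix(stats::rnorm(n_snps * m), n_snps, m) * se

  panel <- effect_panel(data.frame(
    snp = rep(sprintf("snp%04d", seq_len(n_snps)), times = m),
    population = rep(populations, each = n_snps),
    beta = as.vector(y),
    se = as.vector(se),
    stringsAsFactors = FALSE
  ))
  truth <- list(
    true_icc = if (between_sd == 0 && within_sd == 0) NA_real_ else
      between_sd^2 / (between_sd^2 + within_sd^2),
    true_alpha = alpha, seed = as.integer(seed))
  list(panel = panel, truth = truth)
}
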