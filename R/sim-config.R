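#' Simulation configuration for synthetic PRS cohorts
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. Defaults emulate the statistical structure of a large Asian
#' case-control evaluation of a European-derived breast-cancer PRS:
#' 313 candidate SNPs of which 26 fall below the imputation-quality cutoff,
#' about 15\% of European-common SNPs rare in the target population,
#' a per-reference-SD log odds ratio of log(1.52), control PRS standard
#' deviations of 0.597 (reference population) and 0.556 (target population),
#' and case/control counts of 15,755 / 16,483.
#'
#' @param n_snps number of SNPs on the weight panel.
#' @param n_low_info number of SNPs assigned an imputation INFO score below
#'   0.9 (the remainder get INFO in \[0.9, 1\]).
#' @param frac_rare_pop2 fraction of SNPs that are common in population 1
#'   (MAF > 0.05) but rare (MAF < 0.05) in population 2.
#' @param per_sd_log_or log odds ratio per reference-control SD of the PRS.
#' @param control_sd_pop1,control_sd_pop2 target control PRS standard
#'   deviations in the two populations; population 1 is the standardising
#'   (reference) population.
#' @param prs_mean_pop2 mean raw PRS in population-2 controls.
#' @param n_cases,n_controls case-control sample sizes.
#' @param prevalence baseline disease prevalence used when sampling case
#'   status from the finite synthetic population.
#' @param n_strata number of study/array/batch strata.
#' @param er_pos_frac,er_neg_frac fractions of cases labelled ER-positive and
#'   ER-negative (the remainder are of unknown subtype).
#' @param fh_relative_correlation PRS correlation between a woman and her
#'   simulated first-degree relative.
#' @param fh_prevalence marginal prevalence of a positive family history.
#' @param n_women size of the prospective cohort.
#' @param followup_years maximum (administrative) follow-up.
#' @param censoring_rate rate of independent exponential censoring per year.
#' @param event_rate target marginal event rate (events per person-year) in
#'   the prospective cohort.
#' @param entry_age_range age-at-entry range for the prospective cohort.
#' @param seed integer seed; identical configurations generate identical
#'   datasets.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_snps = 313L,
                       n_low_info = min(26L, as.integer(n_snps)),
                       frac_rare_pop2 = 0.15,
                       per_sd_log_or = log(1.52),
                       control_sd_pop1 = 0.597,
                       control_sd_pop2 = 0.556,
                       prs_mean_pop2 = 0.69,
                       n_cases = 15755L,
                       n_controls = 16483L,
                       prevalence = 0.05,
                       n_strata = 5L,
                       er_pos_frac = 0.66,
                       er_neg_frac = 0.30,
                       fh_relative_correlation = 0.5,
                       fh_prevalence = 0.07,
                       n_women = 10255L,
                       followup_years = 19.05,
                       censoring_rate = 0,
                       event_rate = 413 / 195317.2,
                       entry_age_range = c(43, 75),
                       seed = 1L) {
  cfg <- list(
    n_snps = as.integer(n_snps), n_low_info = as.integer(n_low_info),
    frac_rare_pop2 = frac_rare_pop2, per_sd_log_or = per_sd_log_or,
    control_sd_pop1 = control_sd_pop1, control_sd_pop2 = control_sd_pop2,
    prs_mean_pop2 = prs_mean_pop2,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    prevalence = prevalence, n_strata = as.integer(n_strata),
    er_pos_frac = er_pos_frac, er_neg_frac = er_neg_frac,
    fh_relative_correlation = fh_relative_correlation,
    fh_prevalence = fh_prevalence,
    n_women = as.integer(n_women), followup_years = followup_years,
    censoring_rate = censoring_rate, event_rate = event_rate,
    entry_age_range = entry_age_range, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_snps >= 1L,
    cfg$n_low_info >= 0L, cfg$n_low_info <= cfg$n_snps,
    cfg$frac_rare_pop2 >= 0, cfg$frac_rare_pop2 <= 1,
    is.finite(cfg$per_sd_log_or),
    cfg$control_sd_pop1 > 0, cfg$control_sd_pop2 > 0,
    cfg$n_cases >= 1L, cfg$n_controls >= 1L,
    cfg$prevalence > 0, cfg$prevalence < 1,
    cfg$n_strata >= 1L,
    cfg$er_pos_frac >= 0, cfg$er_neg_frac >= 0,
    cfg$er_pos_frac + cfg$er_neg_frac <= 1,
    cfg$fh_relative_correlation >= 0, cfg$fh_relative_correlation <= 1,
    cfg$fh_prevalence > 0, cfg$fh_prevalence < 1,
    cfg$n_women >= 1L, cfg$followup_years > 0,
    cfg$censoring_rate >= 0, cfg$event_rate > 0,
    length(cfg$entry_age_range) == 2L,
    cfg$entry_age_range[1] < cfg$entry_age_range[2]
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  SNPs: %d (%d with INFO < 0.9), frac rare in pop2: %.2f\n",
              x$n_snps, x$n_low_info, x$frac_rare_pop2))
  cat(sprintf("  per-SD log OR: %.4f; control SDs: %.3f (pop1) / %.3f (pop2)\n",
              x$per_sd_log_or, x$control_sd_pop1, x$control_sd_pop2))
  cat(sprintf("  cases/controls: %d/%d at prevalence %.3f; %d strata\n",
              x$n_cases, x$n_controls, x$prevalence, x$n_strata))
  cat(sprintf("  prospective: %d women, %.1fy follow-up, event rate %.5f\n",
              x$n_women, x$followup_years, x$event_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
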