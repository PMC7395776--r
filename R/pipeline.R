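#' Run the end-to-end evaluation pipeline
#'
#' Orchestrates simulate -> score -> associate -> theory -> absolute risk ->
#' concordance from a single configuration, writing intermediate files and
#' a machine-readable JSON report to the output directory. Stages can be
#' toggled; later stages reuse earlier stages' in-memory results. All
#' randomness derives from the configured seed, so a rerun with the same
#' configuration reproduces the report (modulo the timestamp field).
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{integer seed.}
#'     \item{sim}{named list of [sim_config()] overrides.}
#'     \item{stages}{character subset of \code{c("simulate", "score",
#'       "associate", "theory", "absolute_risk", "concordance")}.}
#'     \item{info_threshold}{INFO filter cutoff (default 0.9).}
#'     \item{lambda_fam}{assumed familial relative risk (default 2).}
#'     \item{threshold}{10-year risk screening threshold (default 0.023).}
#'   }
#' @return the report, invisibly (also written as \code{report.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "score", "associate", "theory",
                                 "absolute_risk", "concordance")
  out_dir <- config$out_dir %||% stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  info_threshold <- config$info_threshold %||% 0.9
  lambda_fam <- config$lambda_fam %||% 2
  threshold <- config$threshold %||% 0.023

  cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
  report <- list(seed = seed, stages = stages,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  t0 <- proc.time()[3]
  stage_time <- list()
  tick <- function(name) {
    stage_time[[name]] <<- round(proc.time()[3] - t0, 2)
    t0 <<- proc.time()[3]
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  panel <- cohort <- prospective <- truth <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      panel <<- gen_weight_panel(cfg)
      cc <- gen_case_control_cohort(panel, cfg)
      cohort <<- gen_family_history(cc$cohort, cfg)
      truth <<- cc$truth
      prospective <<- gen_prospective_cohort(panel, cfg)
      write_weight_panel(panel, file.path(out_dir, "weights.tsv"))
      utils::write.table(cohort, file.path(out_dir, "cohort.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(prospective$cohort,
                         file.path(out_dir, "prospective.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      write_rates_table(gen_rates_table(), file.path(out_dir, "rates.csv"))
    })
    tick("simulate")
  }

  if ("score" %in% stages) {
    run_stage("score", function() {
      panel <<- filter_by_info(panel, info_threshold)
      std <- standardize_prs(cohort$prs_raw, cfg$control_sd_pop1)
      cohort$prs <<- std$standardized_value
      prospective$cohort$prs <<-
        prospective$cohort$prs_raw / cfg$control_sd_pop1
      report$prs_summary <<- summarize_prs(
        cohort$prs_raw, ifelse(cohort$status == 1, "case", "control"))
      report$n_snps_after_filter <<- nrow(panel)
    })
    tick("score")
  }

  if ("associate" %in% stages) {
    run_stage("associate", function() {
      per_sd <- fit_logistic_per_sd(cohort)
      bins <- percentile_bin_or(cohort)
      auc <- study_adjusted_auc(cohort$prs, cohort$status, cohort$stratum)
      fh <- fh_attenuation(cohort)
      hr <- fit_cox_per_sd(prospective$cohort)
      per_study <- lapply(split(cohort, cohort$stratum), function(d)
        fit_logistic_per_sd(d, covariates = intersect(paste0("pc", 1:10),
                                                      names(d))))
      meta <- fixed_effect_meta(per_study)
      report$association <<- list(
        or_per_sd = unclass(per_sd)[c("point", "lcl", "ucl")],
        bin_or = bins,
        auc = auc,
        hr_per_sd = unclass(hr)[c("point", "lcl", "ucl")],
        fh_attenuation_pct = fh$attenuation_pct,
        meta = list(pooled = unclass(meta$pooled)[c("point", "lcl", "ucl")],
                    Q = meta$Q, I2 = meta$I2, p_het = meta$p_het))
    })
    tick("associate")
  }

  model <- polygenic_model(
    or_per_sd = exp(cfg$per_sd_log_or),
    control_sd = cfg$control_sd_pop2, reference_sd = cfg$control_sd_pop1,
    prevalence = cfg$prevalence)

  if ("theory" %in% stages) {
    run_stage("theory", function() {
      frr <- frr_explained(model, lambda_fam)
      report$theory <<- list(
        gamma = model$gamma,
        lambda_p = frr$lambda_p,
        frr_fraction = frr$fraction_explained,
        predicted_bin_or = predicted_bin_or(model),
        theoretical_auc = theoretical_auc(model))
    })
    tick("theory")
  }

  if ("absolute_risk" %in% stages) {
    run_stage("absolute_risk", function() {
      rates <- gen_rates_table()
      groups <- centile_risk_groups(model, boundaries = bin_scheme()$boundaries)
      summ <- absolute_risk_summary(rates, groups, threshold)
      elig <- screening_eligibility(model, rates, threshold)
      utils::write.table(summ, file.path(out_dir, "absolute_risk.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$absolute_risk <<- list(
        summary = summ,
        fraction_population_eligible = elig$fraction_population,
        fraction_cases_captured = elig$fraction_cases_captured)
    })
    tick("absolute_risk")
  }

  if ("concordance" %in% stages) {
    run_stage("concordance", function() {
      ep <- gen_effect_panel(n_snps = 100L, seed = seed)
      fit <- em_icc(ep$panel)
      write_effect_panel(ep$panel, file.path(out_dir, "effects.tsv"))
      report$concordance <<- list(icc = fit$icc, sigma2_R = fit$sigma2_R,
                                  converged = fit$converged,
                                  true_icc = ep$truth$true_icc)
    })
    tick("concordance")
  }

  report$stage_seconds <- stage_time
  report$versions <- list(
    package = as.character(utils::packageVersion("prstransfer")),
    r = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
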