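#' Panel of per-SNP effect estimates across populations
#'
#' Long-format data frame with columns \code{snp}, \code{population},
#' \code{beta} (log odds per effect allele) and \code{se} (its known
#' standard error). Missing estimates (e.g. a SNP monomorphic in one
#' population) may be absent or carried as NA rows; they are excluded
#' pairwise by the fitters.
#'
#' @param x data frame as above.
#' @return classed data frame \code{effect_panel}.
#' @export
effect_panel <- function(x) {
  need <- c("snp", "population", "beta", "se")
  if (!all(need %in% names(x)))
    stop("effect panel needs columns: ", paste(need, collapse = ", "))
  ok <- !is.na(x$beta)
  if (any(!is.finite(x$beta[ok]))) stop("non-finite effect estimates")
  if (any(x$se[ok] <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  if (anyDuplicated(x[c("snp", "population")]))
    stop("duplicate (snp, population) rows")
  class(x) <- unique(c("effect_panel", class(x)))
  x
}

.panel_wide <- function(panel) {
  snps <- unique(panel$snp)
  pops <- unique(panel$population)
  y <- se <- matrix(NA_real_, length(snps), length(pops),
                    dimnames = list(snps, pops))
  y[cbind(match(panel$snp, snps), match(panel$population, pops))] <- panel$beta
  se[cbind(match(panel$snp, snps), match(panel$population, pops))] <- panel$se
  list(y = y, se = se)
}

#' Per-SNP logistic effect estimates by population
#'
#' One logistic regression per SNP per population, regressing case status
#' on the effect-allele dosage under a log-additive model, adjusted for
#' age, stratum and the first ten principal components (those present in
#' the cohort). SNPs monomorphic in a population are recorded as missing.
#'
#' @param cohort cohort data frame with \code{status} and covariates; one
#'   population per call (use the \code{population} label for the output).
#' @param dosages a [dosage_matrix()] aligned to the cohort rows.
#' @param panel a [weight_panel()] naming the SNPs to fit.
#' @param population label stored in the output.
#' @param covariates adjustment columns (default: age, stratum, pc1..pc10
#'   where present).
#' @return an [effect_panel()] for this population.
#' @export
fit_per_snp_effects <- function(cohort, dosages, panel, population = "pop",
                                covariates = intersect(
                                  c("age", "stratum", paste0("pc", 1:10)),
                                  names(cohort))) {
  if (length(unique(cohort$status)) != 2L)
    stop("both outcome classes must be present")
  info <- attr(dosages, "variant_info")
  idx <- match(panel$variant_id, info$variant_id)
  if (anyNA(idx)) stop("panel variant(s) missing from dosages")
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(cohort[[v]])) > 1L, logical(1))]
  base <- paste(covariates, collapse = " + ")
  out <- data.frame(snp = panel$variant_id, population = population,
                    beta = NA_real_, se = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    x <- unclass(dosages)[, idx[k]]
    if (stats::var(x) == 0) next  # monomorphic: leave NA
    dat <- cohort
    dat$.dose <- x
    fml <- stats::as.formula(paste("status ~ .dose",
                                   if (nzchar(base)) paste("+", base) else ""))
    fit <- stats::glm(fml, family = stats::binomial(), data = dat)
    cf <- summary(fit)$coefficients
    if (".dose" %in% rownames(cf)) {
      out$beta[k] <- cf[".dose", 1]
      out$se[k] <- cf[".dose", 2]
    }
  }
  effect_panel(out)
}

#' EM fit of the hierarchical measurement-error model and ICC
#'
#' Model: observed estimate \eqn{y_{ij} = \beta_{ij} + \delta_{ij}} for SNP
#' \eqn{i} in population \eqn{j}, with known sampling SDs
#' \eqn{\sigma_{ij}}; the true effects \eqn{\beta_{ij}} scatter about a
#' per-SNP mean \eqn{\alpha_i} with pooled within-SNP variance
#' \eqn{\sigma_R^2}. The E-step shrinks each estimate toward its SNP mean,
#' \deqn{\hat\beta_{ij} = \frac{\alpha_i/\sigma_R^2 + y_{ij}/\sigma_{ij}^2}
#'   {1/\sigma_R^2 + 1/\sigma_{ij}^2},}
#' and the M-step treats the \eqn{\hat\beta_{ij}} as complete data:
#' \eqn{\alpha_i} becomes their per-SNP mean and \eqn{\sigma_R^2} their
#' pooled mean squared deviation about the \eqn{\alpha_i}. Iteration stops
#' when the ICC changes by less than \code{tol}.
#'
#' The ICC is the between-SNP share of variance,
#' \eqn{\mathrm{Var}(\alpha_i) / (\mathrm{Var}(\alpha_i) + \sigma_R^2)},
#' using the unbiased sample variance of the fitted \eqn{\alpha_i}: the
#' concordance of per-SNP effects across populations after accounting for
#' sampling error.
#'
#' @param panel an [effect_panel()] with at least 2 populations and 3 SNPs.
#' @param tol convergence tolerance on the ICC change.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return list \code{icc_fit}: \code{alpha} (per-SNP means),
#'   \code{beta_hat} (shrunken estimates), \code{sigma2_R}, \code{icc},
#'   \code{n_iterations}, \code{converged}.
#' @export
em_icc <- function(panel, tol = 1e-8, max_iter = 1000L) {
  w <- .panel_wide(panel)
  y <- w$y; se <- w$se
  keep <- rowSums(!is.na(y)) >= 1L
  y <- y[keep, , drop = FALSE]; se <- se[keep, , drop = FALSE]
  if (ncol(y) < 2L) stop("need at least 2 populations")
  if (nrow(y) < 3L) stop("need at least 3 SNPs")
  v <- se^2
  obs <- !is.na(y)

  alpha <- rowMeans(y, na.rm = TRUE)
  resid2 <- (y - alpha)^2
  sigma2 <- max(mean(resid2[obs]), 1e-12)
  icc_of <- function(alpha, sigma2) {
    va <- stats::var(alpha)
    if (va + sigma2 <= 0) stop("zero total variance")
    va / (va + sigma2)
  }
  icc <- icc_of(alpha, sigma2)
  converged <- FALSE
  it <- 0L
  beta_hat <- y
  while (it < max_iter) {
    it <- it + 1L
    beta_hat <- (alpha / sigma2 + y / v) / (1 / sigma2 + 1 / v)
    alpha <- rowMeans(beta_hat, na.rm = TRUE)
    sigma2 <- max(mean((beta_hat - alpha)^2, na.rm = TRUE), 1e-12)
    icc_new <- icc_of(alpha, sigma2)
    if (abs(icc_new - icc) < tol) {
      icc <- icc_new
      converged <- TRUE
      break
    }
    icc <- icc_new
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  structure(list(alpha = alpha, beta_hat = beta_hat, sigma2_R = sigma2,
                 icc = icc, n_iterations = it, converged = converged),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("EM hierarchical fit: ICC = %.3f (sigma2_R = %.3g) after %d iterations%s\n",
              x$icc, x$sigma2_R, x$n_iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Read an effect panel from TSV
#'
#' @param path TSV with columns snp, population, beta, se.
#' @return an [effect_panel()].
#' @export
read_effect_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  effect_panel(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write an effect panel to TSV
#'
#' @param panel an [effect_panel()].
#' @param path output path.
#' @export
write_effect_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
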