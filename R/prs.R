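#' Compute raw polygenic risk scores
#'
#' For each individual, the PRS is the weighted sum of effect-allele
#' dosages, \eqn{\mathrm{PRS}_i = \sum_k \beta_k x_{ik}}. Dosage columns
#' whose counted allele is the panel's \emph{other} allele are flipped
#' (\code{x -> 2 - x}) before summing, so scores are invariant to the
#' orientation in which a dosage file was written. Variants whose allele
#' pair matches the panel in neither orientation are an error, as are panel
#' variants absent from the dosage source.
#'
#' Palindromic (A/T, C/G) variants are matched by id first and alleles
#' second; with \code{strict = TRUE} a palindromic variant whose alleles do
#' not match either orientation exactly is rejected rather than scored.
#'
#' @param dosages a [dosage_matrix()].
#' @param panel a [weight_panel()].
#' @param weight_set \code{"overall"}, \code{"erpos"} or \code{"erneg"}.
#' @param strict reject palindromic allele mismatches.
#' @param missing \code{"error"} (default; the intended inputs are fully
#'   imputed) or \code{"impute"}, which substitutes twice the panel
#'   effect-allele frequency (\code{freq_pop2} falling back to
#'   \code{freq_pop1}) for missing dosages.
#' @return numeric vector of raw PRSs, one per individual, named by sample
#'   id when available.
#' @export
compute_prs <- function(dosages, panel,
                        weight_set = c("overall", "erpos", "erneg"),
                        strict = FALSE, missing = c("error", "impute")) {
  missing <- match.arg(missing)
  weight_set <- match.arg(weight_set)
  wcol <- paste0("weight_", weight_set)
  if (!wcol %in% names(panel)) stop("panel has no ", wcol, " column")
  info <- attr(dosages, "variant_info")
  idx <- match(panel$variant_id, info$variant_id)
  if (anyNA(idx))
    stop("variant(s) not resolvable in dosage source: ",
         paste(panel$variant_id[is.na(idx)], collapse = ", "))

  counted <- info$counted_allele[idx]
  other <- info$other_allele[idx]
  same <- counted == panel$effect_allele & other == panel$other_allele
  flipped <- counted == panel$other_allele & other == panel$effect_allele
  palindromic <- (panel$effect_allele == "A" & panel$other_allele == "T") |
    (panel$effect_allele == "T" & panel$other_allele == "A") |
    (panel$effect_allele == "C" & panel$other_allele == "G") |
    (panel$effect_allele == "G" & panel$other_allele == "C")
  bad <- !(same | flipped)
  if (any(bad & (strict | !palindromic)))
    stop("allele pair mismatches panel for: ",
         paste(panel$variant_id[bad & (strict | !palindromic)], collapse = ", "))
  # non-strict palindromic mismatch: trust the id, assume same orientation
  same[bad] <- TRUE

  X <- unclass(dosages)[, idx, drop = FALSE]
  if (anyNA(X)) {
    if (missing == "error")
      stop("missing dosage for resolvable variant(s); rerun with ",
           "missing = \"impute\" to substitute 2 * effect-allele frequency")
    freq <- panel$freq_pop2 %||% panel$freq_pop1
    if (is.null(freq)) stop("impute mode needs a panel frequency column")
    for (k in which(colSums(is.na(X)) > 0)) {
      fill <- 2 * freq[k]
      # X holds the counted-allele dosage; flip the fill for flipped columns
      if (flipped[k] && !same[k]) fill <- 2 - fill
      X[is.na(X[, k]), k] <- fill
    }
  }
  w <- panel[[wcol]]
  # flipped columns: sum w*(2-x) = 2*sum(w_flipped) - sum(w*x)
  signs <- ifelse(flipped & !same, -1, 1)
  offset <- 2 * sum(w[flipped & !same])
  prs <- as.numeric(X %*% (w * signs)) + offset
  names(prs) <- rownames(dosages)
  prs
}

#' Standardise raw PRSs to a reference-control SD
#'
#' Divides each raw score by the standard deviation of the PRS in a
#' reference control population (no mean-centering), so that effect sizes
#' are expressed per reference-control SD.
#'
#' @param raw numeric vector of raw PRSs.
#' @param reference_sd positive reference SD.
#' @param weight_set_tag label recording which weight set produced the raw
#'   scores.
#' @return data frame with \code{raw_value}, \code{standardized_value},
#'   \code{reference_sd} and \code{weight_set_tag}; classed
#'   \code{standardized_prs}.
#' @export
standardize_prs <- function(raw, reference_sd, weight_set_tag = "overall") {
  if (!is.numeric(reference_sd) || length(reference_sd) != 1L ||
      !is.finite(reference_sd) || reference_sd <= 0)
    stop("reference_sd must be a single positive number")
  out <- data.frame(raw_value = as.numeric(raw),
                    standardized_value = as.numeric(raw) / reference_sd,
                    reference_sd = reference_sd,
                    weight_set_tag = weight_set_tag,
                    stringsAsFactors = FALSE)
  if (!is.null(names(raw))) out$sample_id <- names(raw)
  class(out) <- c("standardized_prs", class(out))
  out
}

#' Per-group mean and SD of a PRS
#'
#' @param prs numeric vector of scores.
#' @param grouping factor-like vector of the same length (e.g. case/control
#'   status, ethnicity).
#' @return data frame with \code{group}, \code{n}, \code{mean}, \code{sd}
#'   (unbiased, denominator n-1).
#' @export
summarize_prs <- function(prs, grouping) {
  stopifnot(length(prs) == length(grouping))
  grouping <- as.factor(grouping)
  if (any(table(grouping) < 2))
    stop("every group needs at least 2 members for an SD")
  out <- data.frame(
    group = levels(grouping),
    n = as.integer(table(grouping)),
    mean = as.numeric(tapply(prs, grouping, mean)),
    sd = as.numeric(tapply(prs, grouping, stats::sd)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
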