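#' SNP weight panel
#'
#' A data frame of scoring weights, one row per variant, with columns
#' \code{variant_id}, \code{chr}, \code{pos}, \code{effect_allele},
#' \code{other_allele}, \code{weight_overall}, \code{weight_erpos},
#' \code{weight_erneg}, \code{info}, \code{freq_pop1}, \code{freq_pop2}.
#' Weights are per-allele log odds ratios: the PRS of an individual is
#' \eqn{\sum_k \beta_k x_k} over the panel, \eqn{x_k} being the dosage
#' (0-2) of the effect allele.
#'
#' @param x data frame with the columns above.
#' @return the validated panel, classed \code{weight_panel}.
#' @export
weight_panel <- function(x) {
  required <- c("variant_id", "effect_allele", "other_allele",
                "weight_overall", "info")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)
  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup))
    stop("duplicated variant_id: ", paste(unique(dup), collapse = ", "))
  if (any(x$effect_allele == x$other_allele))
    stop("effect_allele equals other_allele for: ",
         paste(x$variant_id[x$effect_allele == x$other_allele], collapse = ", "))
  for (w in intersect(c("weight_overall", "weight_erpos", "weight_erneg"),
                      names(x))) {
    if (!is.numeric(x[[w]]) || any(!is.finite(x[[w]])))
      stop("non-finite or non-numeric ", w)
  }
  if (any(x$info < 0 | x$info > 1)) stop("info scores must lie in [0,1]")
  class(x) <- unique(c("weight_panel", class(x)))
  x
}

#' Read a scoring weight file
#'
#' Tab-separated, one row per variant, header mandatory. Allele columns are
#' uppercased; duplicate variant ids and non-numeric weights are errors
#' naming the offending rows.
#'
#' @param path file path.
#' @return a [weight_panel()].
#' @export
read_weight_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  weight_panel(x)
}

#' Write a scoring weight file
#'
#' @param panel a [weight_panel()].
#' @param path output path (TSV).
#' @export
write_weight_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  for (j in seq_along(out))  # %.17g round-trips doubles exactly
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop variants below an imputation-quality threshold
#'
#' Retains exactly the variants with INFO score at or above the threshold,
#' preserving panel order. An empty result is allowed.
#'
#' @param panel a [weight_panel()].
#' @param threshold INFO cutoff in \[0,1\] (default 0.9).
#' @return the filtered panel.
#' @export
filter_by_info <- function(panel, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  panel[panel$info >= threshold, , drop = FALSE]
}

#' Restrict a panel to variants available in a dosage source
#'
#' Keeps panel variants that are present and non-monomorphic in the dosage
#' matrix. Weights are not rescaled for the variants lost: scores built on
#' the reduced set are compared unrenormalised with scores from the full
#' set.
#'
#' @param panel a [weight_panel()].
#' @param dosages a [dosage_matrix()].
#' @return the restricted panel.
#' @export
restrict_to_available <- function(panel, dosages) {
  info <- attr(dosages, "variant_info")
  present <- panel$variant_id %in% info$variant_id
  if (!any(present)) stop("no panel variant is present in the dosage source")
  keep <- panel$variant_id[present]
  mono <- vapply(keep, function(v) {
    x <- dosages[, match(v, info$variant_id)]
    stats::var(x) == 0
  }, logical(1))
  panel[panel$variant_id %in% keep[!mono], , drop = FALSE]
}
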