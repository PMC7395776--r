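#' Allele-dosage matrix
#'
#' Individuals by variants matrix of expected allele counts in \[0,2\], with
#' per-variant orientation metadata: the \emph{counted} allele is the allele
#' whose dosage the matrix stores, so a scorer can flip (\code{x -> 2 - x})
#' when a weight panel counts the opposite allele.
#'
#' @param x numeric matrix, rows = individuals, columns = variants.
#' @param variant_info data frame with \code{variant_id},
#'   \code{counted_allele}, \code{other_allele} (one row per column of
#'   \code{x}).
#' @param sample_ids character vector of row identifiers.
#' @return classed matrix with attributes \code{variant_info} and row/col
#'   names set.
#' @export
dosage_matrix <- function(x, variant_info, sample_ids = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(variant_info))
    stop("variant_info must have one row per dosage column")
  stopifnot(all(c("variant_id", "counted_allele", "other_allele") %in%
                  names(variant_info)))
  if (any(x < 0 | x > 2, na.rm = TRUE)) stop("dosages must lie in [0,2]")
  if (anyDuplicated(variant_info$variant_id))
    stop("duplicated variant ids in dosage source")
  variant_info$counted_allele <- toupper(variant_info$counted_allele)
  variant_info$other_allele <- toupper(variant_info$other_allele)
  colnames(x) <- variant_info$variant_id
  if (!is.null(sample_ids)) rownames(x) <- sample_ids
  attr(x, "variant_info") <- variant_info
  class(x) <- c("dosage_matrix", class(x))
  x
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d variants\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Write dosages as a plain TSV matrix
#'
#' First three columns carry the variant metadata (variant_id,
#' counted_allele, other_allele); remaining columns are individuals.
#'
#' @param dosages a [dosage_matrix()].
#' @param path output path.
#' @export
write_dosage_tsv <- function(dosages, path) {
  info <- attr(dosages, "variant_info")
  out <- cbind(info[c("variant_id", "counted_allele", "other_allele")],
               as.data.frame(t(unclass(dosages))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read dosages from a plain TSV matrix
#'
#' @param path file written by [write_dosage_tsv()].
#' @return a [dosage_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("variant_id", "counted_allele", "other_allele")
  if (!all(meta %in% names(x))) stop("missing dosage metadata columns")
  mat <- t(as.matrix(x[, setdiff(names(x), meta), drop = FALSE]))
  dosage_matrix(mat, variant_info = x[meta], sample_ids = rownames(mat))
}

#' Write dosages as a VCF with a DS FORMAT field
#'
#' Minimal VCFv4.2 with REF = counted allele, ALT = other allele and the
#' per-sample dosage of REF stored in DS. Note VCF convention stores the
#' ALT dosage; here DS is declared (in the header) to carry the counted
#' (REF) allele dosage written by this package, and [read_dosage_vcf()]
#' reads it back under the same convention.
#'
#' @param dosages a [dosage_matrix()].
#' @param path output path (plain text).
#' @param chr,pos optional coordinates (defaults enumerate).
#' @export
write_dosage_vcf <- function(dosages, path, chr = NULL, pos = NULL) {
  info <- attr(dosages, "variant_info")
  n_var <- ncol(dosages)
  if (is.null(chr)) chr <- rep(1L, n_var)
  if (is.null(pos)) pos <- seq_len(n_var)
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- sprintf("S%06d", seq_len(nrow(dosages)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the REF (counted) allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(n_var), function(j) {
    paste(c(chr[j], pos[j], info$variant_id[j], info$counted_allele[j],
            info$other_allele[j], ".", "PASS", ".", "DS",
            format(unclass(dosages)[, j], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF DS field
#'
#' Uses \pkg{vcfR} for parsing. The counted allele is taken to be REF,
#' matching [write_dosage_vcf()]; for external VCFs whose DS stores the ALT
#' dosage, set \code{counted = "alt"}.
#'
#' @param path VCF path.
#' @param counted which allele the DS field counts, \code{"ref"} or
#'   \code{"alt"}.
#' @return a [dosage_matrix()].
#' @export
read_dosage_vcf <- function(path, counted = c("ref", "alt")) {
  counted <- match.arg(counted)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  if (counted == "ref") {
    ca <- fix[, "REF"]; oa <- fix[, "ALT"]
  } else {
    ca <- fix[, "ALT"]; oa <- fix[, "REF"]
  }
  dosage_matrix(t(ds),
                variant_info = data.frame(variant_id = fix[, "ID"],
                                          counted_allele = ca,
                                          other_allele = oa,
                                          stringsAsFactors = FALSE),
                sample_ids = colnames(ds))
}
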