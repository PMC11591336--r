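#' Construct a genotype dataset
#'
#' The central container of the package: a samples x SNPs matrix of
#' allele-dosage calls (copies of \code{allele2}, i.e. 0, 1, 2 or \code{NA}
#' for a missing genotype) together with the SNP map and per-sample
#' population and case/control group labels.
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param samples data.frame with columns \code{id}, \code{family},
#'   \code{population}, \code{group}; \code{group} must be one of
#'   \code{"case"}, \code{"control"}, \code{"unassigned"}.
#' @param snps data.frame with columns \code{chrom} (positive integer),
#'   \code{id}, \code{cm} (genetic position), \code{bp} (physical position,
#'   >= 1), \code{allele1}, \code{allele2}.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!"family" %in% names(samples)) samples$family <- samples$id
  if (!"group" %in% names(samples)) samples$group <- "unassigned"
  if (!"population" %in% names(samples)) samples$population <- "unassigned"
  ds <- structure(list(calls = calls, samples = samples, snps = snps),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset
#'
#' Checks the structural invariants: matching dimensions, legal call values,
#' SNPs strictly sorted by (chromosome, bp) with no duplicate positions, and
#' legal group labels.
#'
#' @param ds a \code{genotype_dataset}.
#' @return \code{ds}, invisibly; errors on violation.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  need_s <- c("id", "family", "population", "group")
  need_m <- c("chrom", "id", "cm", "bp", "allele1", "allele2")
  if (!all(need_s %in% names(ds$samples)))
    stop("samples table must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_m %in% names(ds$snps)))
    stop("snps table must have columns: ", paste(need_m, collapse = ", "))
  if (nrow(ds$calls) != nrow(ds$samples))
    stop("calls rows (", nrow(ds$calls), ") != samples (", nrow(ds$samples), ")")
  if (ncol(ds$calls) != nrow(ds$snps))
    stop("calls columns (", ncol(ds$calls), ") != snps (", nrow(ds$snps), ")")
  vals <- ds$calls[!is.na(ds$calls)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("calls must be 0, 1, 2 or NA")
  if (!all(ds$samples$group %in% c("case", "control", "unassigned")))
    stop("sample group labels must be case/control/unassigned")
  if (nrow(ds$snps)) {
    if (any(ds$snps$bp < 1)) stop("bp positions must be >= 1")
    if (any(ds$snps$chrom < 1)) stop("chromosome codes must be positive")
    o <- order(ds$snps$chrom, ds$snps$bp)
    if (!identical(o, seq_len(nrow(ds$snps))))
      stop("SNPs must be sorted by (chromosome, bp)")
    key <- paste(ds$snps$chrom, ds$snps$bp)
    if (anyDuplicated(key)) stop("duplicate (chromosome, bp) positions")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x", nrow(x$snps), "SNPs\n")
  cat("  populations:", paste(sort(unique(x$samples$population)), collapse = ", "), "\n")
  grp <- table(factor(x$samples$group, c("case", "control", "unassigned")))
  cat("  groups: case", grp[["case"]], "/ control", grp[["control"]],
      "/ unassigned", grp[["unassigned"]], "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", if (length(x$calls)) miss else 0))
  invisible(x)
}

#' Number of samples and SNPs
#' @param ds a \code{genotype_dataset}.
#' @return integer vector \code{c(samples, snps)}.
#' @export
dim_dataset <- function(ds) c(nrow(ds$samples), nrow(ds$snps))

#' Subset a genotype dataset
#'
#' @param ds a \code{genotype_dataset}.
#' @param samples,snps logical or integer index over samples / SNPs
#'   (default: keep all).
#' @return the subsetted \code{genotype_dataset}.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(ds$samples))
  if (is.null(snps)) snps <- seq_len(nrow(ds$snps))
  out <- ds
  out$calls <- ds$calls[samples, snps, drop = FALSE]
  out$samples <- ds$samples[samples, , drop = FALSE]
  out$snps <- ds$snps[snps, , drop = FALSE]
  rownames(out$samples) <- NULL
  rownames(out$snps) <- NULL
  out
}

#' Per-SNP allele frequency of allele2
#'
#' @param ds a \code{genotype_dataset}.
#' @param samples optional sample index to restrict to.
#' @return numeric vector of allele2 frequencies (NaN where all calls missing).
#' @export
allele_freq <- function(ds, samples = NULL) {
  m <- if (is.null(samples)) ds$calls else ds$calls[samples, , drop = FALSE]
  colMeans(m, na.rm = TRUE) / 2
}

#' Identify monomorphic SNPs
#'
#' A SNP is monomorphic when every non-missing call carries the same allele
#' content (frequency 0 or 1). Such SNPs are retained by QC but are undefined
#' for differentiation statistics.
#'
#' @param ds a \code{genotype_dataset}.
#' @return logical vector over SNPs.
#' @export
monomorphic_snps <- function(ds) {
  p <- allele_freq(ds)
  !is.finite(p) | p == 0 | p == 1
}
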