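# Quality control, KING-robust relatedness, and case/control grouping.

#' Quality-control filter
#'
#' Applies the standard SNP-array filters in a fixed order, each computed on
#' the set surviving the previous step: (1) samples with missingness strictly
#' greater than \code{sample_missing_max}; (2) SNPs with call rate strictly
#' below \code{snp_callrate_min}; (3) SNPs with minor allele frequency
#' strictly below \code{maf_min}, pooled over all retained samples. Removal
#' is by strict inequality, so a SNP at exactly the MAF threshold is kept.
#' Monomorphic SNPs that survive (possible when \code{maf_min = 0}) are
#' retained but flagged via \code{\link{monomorphic_snps}} downstream.
#'
#' @param ds a \code{genotype_dataset}.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param snp_callrate_min minimum SNP call rate (default 0.95).
#' @param sample_missing_max maximum per-sample missing fraction
#'   (default 0.05).
#' @return list with elements \code{dataset} (filtered
#'   \code{genotype_dataset}) and \code{report} (a \code{qc_report}: counts
#'   and identifier lists per filter).
#' @export
qc_filter <- function(ds, maf_min = 0.05, snp_callrate_min = 0.95,
                      sample_missing_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_callrate_min >= 0,
            snp_callrate_min <= 1, sample_missing_max >= 0,
            sample_missing_max <= 1)
  n_in <- nrow(ds$samples)
  m_in <- nrow(ds$snps)

  miss_s <- rowMeans(is.na(ds$calls))
  drop_s <- miss_s > sample_missing_max
  removed_samples <- ds$samples$id[drop_s]
  ds1 <- subset_dataset(ds, samples = !drop_s)
  if (nrow(ds1$samples) == 0) {
    rep0 <- .qc_report(n_in, m_in, removed_samples, character(0),
                       character(0), character(0), 0L, 0L)
    stop(errorCondition("qc_filter removed every sample", report = rep0,
                        class = "sweepscan_qc_error"))
  }

  callrate <- 1 - colMeans(is.na(ds1$calls))
  drop_cr <- callrate < snp_callrate_min
  removed_callrate <- ds1$snps$id[drop_cr]
  ds2 <- subset_dataset(ds1, snps = !drop_cr)

  p <- allele_freq(ds2)
  maf <- pmin(p, 1 - p)
  maf[!is.finite(maf)] <- 0
  drop_maf <- maf < maf_min
  removed_maf <- ds2$snps$id[drop_maf]
  ds3 <- subset_dataset(ds2, snps = !drop_maf)

  report <- .qc_report(n_in, m_in, removed_samples, removed_callrate,
                       removed_maf, character(0),
                       nrow(ds3$samples), nrow(ds3$snps))
  list(dataset = ds3, report = report)
}

.qc_report <- function(n_in, m_in, rem_samp, rem_cr, rem_maf, rem_rel,
                       n_out, m_out) {
  structure(list(
    n_snps_input = m_in,
    n_snps_removed_callrate = length(rem_cr),
    n_snps_removed_maf = length(rem_maf),
    n_snps_output = m_out,
    n_samples_input = n_in,
    n_samples_removed_missing = length(rem_samp),
    n_samples_removed_relatedness = length(rem_rel),
    n_samples_output = n_out,
    removed = list(samples_missing = rem_samp, snps_callrate = rem_cr,
                   snps_maf = rem_maf, samples_relatedness = rem_rel)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  SNPs:   ", x$n_snps_input, "in;", x$n_snps_removed_callrate,
      "call-rate;", x$n_snps_removed_maf, "MAF;", x$n_snps_output, "out\n")
  cat("  samples:", x$n_samples_input, "in;", x$n_samples_removed_missing,
      "missingness;", x$n_samples_removed_relatedness, "relatedness;",
      x$n_samples_output, "out\n")
  invisible(x)
}

#' KING-robust pairwise kinship
#'
#' The between-family robust kinship estimator: for samples i and j, over
#' SNPs non-missing in both,
#' \deqn{\hat\phi_{ij} = (N_{het,het} - 2 N_{opp}) / (N_{het}(i) + N_{het}(j))}
#' where \eqn{N_{het,het}} counts SNPs at which both are heterozygous,
#' \eqn{N_{opp}} counts opposite homozygotes, and \eqn{N_{het}(i)} counts
#' heterozygous SNPs of sample i within the jointly non-missing set.
#' Duplicates/monozygotes give 0.5; unrelated pairs about 0; negative values
#' indicate ancestry divergence. The diagonal is fixed at 0.5.
#'
#' @param ds a \code{genotype_dataset} (at least 2 samples).
#' @return symmetric samples x samples matrix; \code{NA} where a pair shares
#'   no jointly non-missing SNP or has no heterozygous calls.
#' @export
king_kinship <- function(ds) {
  n <- nrow(ds$samples)
  stopifnot(n >= 2)
  x <- ds$calls
  obs <- !is.na(x)
  het <- (x == 1L) & obs
  hom0 <- (x == 0L) & obs
  hom2 <- (x == 2L) & obs
  mode(obs) <- "numeric"; mode(het) <- "numeric"
  mode(hom0) <- "numeric"; mode(hom2) <- "numeric"
  n_hethet <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2)
  n_opp <- n_opp + t(n_opp)
  # het counts of i restricted to sites observed in j (and vice versa)
  het_i <- tcrossprod(het, obs)
  denom <- het_i + t(het_i)
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  joint <- tcrossprod(obs)
  phi[joint == 0] <- NA_real_
  diag(phi) <- 0.5
  dimnames(phi) <- list(ds$samples$id, ds$samples$id)
  phi
}

#' Greedy pruning of related samples
#'
#' Removes samples until no retained pair has kinship above
#' \code{threshold}. At each step the sample with the most above-threshold
#' partners is removed (ties broken by sample order), which tends to keep
#' the larger number of samples.
#'
#' @param ds a \code{genotype_dataset}.
#' @param kinship matrix from \code{\link{king_kinship}} on \code{ds}.
#' @param threshold kinship cutoff; the default 0.354 removes only
#'   duplicate/monozygotic pairs (midpoint between first-degree 0.25 and
#'   duplicate 0.5 on the KING log2 scale).
#' @return list with \code{dataset} (pruned) and \code{removed} (character
#'   vector of removed sample ids, in removal order).
#' @export
prune_related <- function(ds, kinship, threshold = 0.354) {
  n <- nrow(ds$samples)
  stopifnot(nrow(kinship) == n, ncol(kinship) == n)
  adj <- !is.na(kinship) & kinship > threshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, n)
  removed <- integer(0)
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    worst <- which.max(deg)  # first index on ties
    keep[worst] <- FALSE
    removed <- c(removed, worst)
  }
  list(dataset = subset_dataset(ds, samples = keep),
       removed = ds$samples$id[removed])
}

#' Assign case/control groups from total prolificacy
#'
#' Labels each sample by its total prolificacy (TP: lifetime lamb count):
#' \code{TP <= low_max} is a control, \code{TP >= high_min} a case, and
#' anything in between (or unphenotyped) stays unassigned and is excluded
#' from the scans.
#'
#' @param ds a \code{genotype_dataset}.
#' @param phenotypes named integer vector (sample id -> TP), a two-column
#'   data.frame, or the path of a two-column whitespace-separated file.
#' @param low_max maximum TP for controls (default 3).
#' @param high_min minimum TP for cases (default 7).
#' @return the dataset with updated \code{samples$group}.
#' @export
assign_groups <- function(ds, phenotypes, low_max = 3, high_min = 7) {
  stopifnot(low_max < high_min)
  if (is.character(phenotypes) && length(phenotypes) == 1L &&
      file.exists(phenotypes)) {
    tab <- utils::read.table(phenotypes, header = FALSE,
                             stringsAsFactors = FALSE)
    phenotypes <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  } else if (is.data.frame(phenotypes)) {
    phenotypes <- stats::setNames(as.numeric(phenotypes[[2]]),
                                  as.character(phenotypes[[1]]))
  }
  absent <- setdiff(names(phenotypes), ds$samples$id)
  if (length(absent))
    warning("phenotyped sample(s) absent from dataset: ",
            paste(absent, collapse = ", "))
  tp <- phenotypes[match(ds$samples$id, names(phenotypes))]
  grp <- rep("unassigned", nrow(ds$samples))
  grp[!is.na(tp) & tp <= low_max] <- "control"
  grp[!is.na(tp) & tp >= high_min] <- "case"
  ds$samples$group <- grp
  ds
}
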