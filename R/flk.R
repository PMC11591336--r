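# Population kinship from Reynolds distances and a midpoint-rooted NJ tree;
# FLK on allele frequencies; hapFLK on haplotype-cluster frequencies;
# genome-wide standardization and p-values.

#' Per-population allele frequencies
#'
#' @param ds a \code{genotype_dataset}.
#' @param by \code{"population"} (default) or \code{"group"}.
#' @return populations x SNPs matrix of allele2 frequencies (\code{NaN}
#'   where a population has no non-missing call).
#' @export
pop_allele_freqs <- function(ds, by = c("population", "group")) {
  by <- match.arg(by)
  labels <- if (by == "population") ds$samples$population else ds$samples$group
  if (by == "group") labels[labels == "unassigned"] <- NA
  lev <- sort(unique(labels[!is.na(labels)]))
  out <- matrix(NA_real_, length(lev), nrow(ds$snps),
                dimnames = list(lev, ds$snps$id))
  for (i in seq_along(lev)) {
    out[i, ] <- allele_freq(ds, samples = which(labels == lev[i]))
  }
  out
}

#' Reynolds coancestry distance between populations
#'
#' For populations A, B over loci l (biallelic here, summing over both
#' alleles):
#' \deqn{D_{AB} = \frac{\sum_l \sum_{alleles} (p_{Al} - p_{Bl})^2}
#'                     {2 \sum_l (1 - \sum_{alleles} p_{Al} p_{Bl})}}
#'
#' @param freqs populations x SNPs allele-frequency matrix (rows named by
#'   population). Loci with a missing frequency in either population of a
#'   pair are excluded for that pair.
#' @return symmetric distance matrix with zero diagonal.
#' @export
reynolds_distance <- function(freqs) {
  P <- nrow(freqs)
  stopifnot(P >= 2)
  D <- matrix(0, P, P, dimnames = list(rownames(freqs), rownames(freqs)))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      pa <- freqs[i, ]; pb <- freqs[j, ]
      ok <- is.finite(pa) & is.finite(pb)
      if (!any(ok)) stop("no jointly defined locus for populations ",
                         rownames(freqs)[i], " and ", rownames(freqs)[j])
      pa <- pa[ok]; pb <- pb[ok]
      num <- sum(2 * (pa - pb)^2)
      den <- 2 * sum(1 - (pa * pb + (1 - pa) * (1 - pb)))
      if (den == 0) stop("Reynolds denominator is zero (all loci fixed ",
                         "identically) for populations ",
                         rownames(freqs)[i], " and ", rownames(freqs)[j])
      D[i, j] <- D[j, i] <- num / den
    }
  }
  D
}

#' Population kinship model from a distance matrix
#'
#' Builds a neighbor-joining tree from the Reynolds distances, roots it at
#' the midpoint (no outgroup), clamps any negative branch length to zero,
#' and assembles the drift covariance matrix F: \eqn{F_{ij}} is the shared
#' drift from the root to the most recent common ancestor of populations i
#' and j, and \eqn{F_{ii}} the root-to-tip drift.
#'
#' The Reynolds distance between two populations that have each accrued
#' drift \eqn{f_A}, \eqn{f_B} since their split converges to
#' \eqn{(f_A+f_B)/2}, the average (not the sum) of the branch drifts, so
#' the NJ path lengths are doubled to put F on the additive drift scale
#' where \eqn{Var(p_i) = F_{ii}\, p_0(1-p_0)}. This is what makes the FLK
#' statistic approximately chi-square with (populations - 1) degrees of
#' freedom under neutrality.
#'
#' @param D symmetric distance matrix (>= 2 populations). With exactly two
#'   populations the tree is a two-tip star with branch lengths D/2
#'   (drift D each after scaling).
#' @param rooting rooting rule; only \code{"midpoint"} is available.
#' @return object of class \code{kinship_model}: list with
#'   \code{populations}, \code{D}, \code{tree} (an \pkg{ape} \code{phylo}),
#'   \code{F}.
#' @export
build_kinship <- function(D, rooting = "midpoint") {
  rooting <- match.arg(rooting, "midpoint")
  if (any(!is.finite(D))) stop("non-finite distances")
  pops <- rownames(D) %||% paste0("pop", seq_len(nrow(D)))
  P <- nrow(D)
  stopifnot(P >= 2, ncol(D) == P)
  if (P == 2) {
    b <- D[1, 2] / 2
    tree <- ape::read.tree(
      text = sprintf("(%s:%f,%s:%f);", pops[1], b, pops[2], b))
    F_mat <- matrix(0, 2, 2, dimnames = list(pops, pops))
    diag(F_mat) <- 2 * b
    return(structure(list(populations = pops, D = D, tree = tree, F = F_mat),
                     class = "kinship_model"))
  }
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    message("build_kinship: clamped ", sum(tree$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree <- phangorn::midpoint(tree)
  tree$edge.length[tree$edge.length < 0] <- 0
  depth <- ape::node.depth.edgelength(tree)  # distance from root per node
  tipidx <- match(pops, tree$tip.label)
  mrca <- ape::mrca(tree)
  F_mat <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      F_mat[i, j] <- if (i == j) 2 * depth[tipidx[i]]
                     else 2 * depth[mrca[tipidx[i], tipidx[j]]]
    }
  }
  structure(list(populations = pops, D = D, tree = tree, F = F_mat),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat("kinship_model:", length(x$populations), "populations:",
      paste(x$populations, collapse = ", "), "\n")
  cat("  root-to-tip drift (F_ii):",
      paste(sprintf("%.4f", diag(x$F)), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a kinship model from a genotype dataset
#'
#' Convenience wrapper: per-population allele frequencies, Reynolds
#' distances, NJ tree, midpoint root, F matrix.
#'
#' @param ds a \code{genotype_dataset}.
#' @param by passed to \code{\link{pop_allele_freqs}}.
#' @return a \code{kinship_model}.
#' @export
kinship_from_dataset <- function(ds, by = "population") {
  build_kinship(reynolds_distance(pop_allele_freqs(ds, by)))
}

.solve_F <- function(F_mat, pops) {
  out <- tryCatch(solve(F_mat), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    # name the most collinear pair for the diagnostic
    sim <- stats::cov2cor(F_mat + diag(1e-12, nrow(F_mat)))
    diag(sim) <- 0
    worst <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    stop("singular kinship matrix F; populations '", pops[worst[1]],
         "' and '", pops[worst[2]], "' have (near-)identical drift")
  }
  out
}

#' FLK test on allele frequencies
#'
#' The extension of the Lewontin-Krakauer test that whitens the population
#' allele-frequency deviations by the kinship matrix F. Per SNP with
#' frequency vector p over populations:
#' \deqn{\hat p_0 = \frac{1^T F^{-1} p}{1^T F^{-1} 1}, \quad
#'   FLK = (p - \hat p_0 1)^T [\hat p_0 (1-\hat p_0) F]^{-1} (p - \hat p_0 1)}
#' approximately chi-square with (number of populations - 1) degrees of
#' freedom under neutrality. SNPs whose estimated ancestral frequency is 0
#' or 1 are undefined.
#'
#' @param freqs populations x SNPs allele-frequency matrix (rows must match
#'   the kinship model's populations).
#' @param kin a \code{kinship_model}.
#' @return data.frame with \code{snp}, \code{stat}, \code{pvalue},
#'   \code{defined}; degrees of freedom in attribute \code{"df"}.
#' @export
flk <- function(freqs, kin) {
  stopifnot(inherits(kin, "kinship_model"))
  if (!is.matrix(freqs)) freqs <- matrix(freqs, ncol = 1)
  P <- nrow(freqs)
  stopifnot(P == length(kin$populations))
  if (!is.null(rownames(freqs)))
    freqs <- freqs[kin$populations, , drop = FALSE]
  Finv <- .solve_F(kin$F, kin$populations)
  w <- Finv %*% rep(1, P)
  p0 <- as.vector(crossprod(w, freqs)) / sum(w)
  R <- freqs - matrix(p0, P, ncol(freqs), byrow = TRUE)
  quad <- colSums(R * (Finv %*% R))
  defined <- is.finite(p0) & p0 > 0 & p0 < 1 &
    apply(is.finite(freqs), 2, all)
  stat <- ifelse(defined, quad / (p0 * (1 - p0)), NA_real_)
  df <- P - 1
  pval <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  out <- data.frame(snp = seq_len(ncol(freqs)), stat = stat, pvalue = pval,
                    defined = defined)
  attr(out, "df") <- df
  out
}

.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' hapFLK test on haplotype-cluster frequencies
#'
#' Extends the FLK quadratic form to the stacked (K-1)-dimensional
#' cluster-frequency residuals per population, with covariance
#' \eqn{S \otimes F} where \eqn{S = Diag(q) - qq^T} (truncated to K-1
#' dimensions) is built from the kinship-weighted ancestral cluster
#' frequencies q. The per-SNP statistic is averaged over the EM runs.
#' A pseudo-inverse replaces the inverse of S at rank-deficient SNPs (the
#' count is reported via a message).
#'
#' @param cfreqs a \code{cluster_freqs} from
#'   \code{\link{cluster_freqs_by_pop}}.
#' @param kin a \code{kinship_model} over the same populations.
#' @return data.frame with \code{snp}, \code{raw} (mean over runs) and the
#'   per-run matrix in attribute \code{"per_run"}.
#' @export
hapflk <- function(cfreqs, kin) {
  stopifnot(inherits(cfreqs, "cluster_freqs"), inherits(kin, "kinship_model"))
  if (!setequal(cfreqs$populations, kin$populations))
    stop("cluster frequencies and kinship model disagree on populations")
  K <- cfreqs$K
  L <- dim(cfreqs$freqs[[1]])[1]
  if (K == 1) {
    out <- data.frame(snp = seq_len(L), raw = rep(0, L))
    attr(out, "per_run") <- matrix(0, L, cfreqs$n_runs)
    return(out)
  }
  pop_idx <- match(kin$populations, cfreqs$populations)
  P <- length(pop_idx)
  Finv <- .solve_F(kin$F, kin$populations)
  w <- as.vector(Finv %*% rep(1, P))
  sw <- sum(w)
  kk <- seq_len(K - 1)
  per_run <- matrix(NA_real_, L, cfreqs$n_runs)
  n_pinv <- 0L
  for (r in seq_len(cfreqs$n_runs)) {
    arr <- cfreqs$freqs[[r]]
    for (l in seq_len(L)) {
      pm <- t(matrix(arr[l, , pop_idx], K, P))  # P x K
      q <- as.vector(crossprod(pm, w)) / sw
      S <- diag(q[kk], K - 1) - tcrossprod(q[kk])
      Rm <- pm[, kk, drop = FALSE] -
        matrix(q[kk], P, K - 1, byrow = TRUE)
      Sinv <- tryCatch(solve(S), error = function(e) NULL)
      if (is.null(Sinv)) { Sinv <- .pinv(S); n_pinv <- n_pinv + 1L }
      per_run[l, r] <- sum((Finv %*% Rm) * (Rm %*% Sinv))
    }
  }
  if (n_pinv > 0)
    message("hapflk: pseudo-inverse used at ", n_pinv,
            " (SNP, run) combinations")
  out <- data.frame(snp = seq_len(L), raw = rowMeans(per_run))
  attr(out, "per_run") <- per_run
  out
}

#' Standardize a genome-wide statistic
#'
#' \deqn{Z = (raw - mean(raw)) / SD(raw)} with the sample standard
#' deviation, then upper-tail p-values: by default from the standard normal
#' on Z (\code{law = "normal"}); \code{law = "chisq"} instead evaluates the
#' raw values against a chi-square with \code{df} degrees of freedom. SNPs
#' in the top \code{top_fraction} of the statistic are flagged.
#'
#' @param raw numeric vector (length >= 2, positive SD).
#' @param law \code{"normal"} (default) or \code{"chisq"}.
#' @param df degrees of freedom for \code{law = "chisq"}.
#' @param top_fraction fraction of SNPs to flag (default 0.001).
#' @return list with \code{z}, \code{pvalue}, \code{flagged} (logical),
#'   \code{threshold} (statistic value at the flag boundary).
#' @export
standardize <- function(raw, law = c("normal", "chisq"), df = NULL,
                        top_fraction = 0.001) {
  law <- match.arg(law)
  ok <- is.finite(raw)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  mu <- mean(raw[ok])
  sdev <- stats::sd(raw[ok])
  if (sdev == 0) stop("zero standard deviation; cannot standardize")
  z <- (raw - mu) / sdev
  pval <- if (law == "normal") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    if (is.null(df)) stop("law = 'chisq' requires df")
    stats::pchisq(raw, df = df, lower.tail = FALSE)
  }
  k <- max(1L, ceiling(top_fraction * sum(ok)))
  thr <- sort(raw[ok], decreasing = TRUE)[k]
  flagged <- ok & raw >= thr
  list(z = z, pvalue = pval, flagged = flagged, threshold = thr)
}

#' Run the full hapFLK scan
#'
#' Fits the haplotype-cluster model, extracts per-population cluster
#' frequencies, computes hapFLK against the kinship model, standardizes
#' genome-wide, and merges flagged SNPs into regions (consecutive flagged
#' SNPs on a chromosome, allowing single-SNP regions).
#'
#' @param x input for \code{\link{em_fit}} (dataset or haplotype set) that
#'   carries population labels.
#' @param kin a \code{kinship_model}; defaults to fitting one from the
#'   input's population allele frequencies.
#' @param K,n_runs,max_iter,tol,seed EM settings (see \code{\link{em_fit}}).
#' @param top_fraction flagged fraction for \code{\link{standardize}}.
#' @param law p-value law for \code{\link{standardize}}.
#' @return list with \code{models}, \code{cluster_freqs}, \code{kinship},
#'   \code{per_snp} (snp, chrom, bp, raw, z, pvalue, flagged),
#'   \code{regions}.
#' @export
hapflk_scan <- function(x, kin = NULL, K = 10, n_runs = 20, max_iter = 100,
                        tol = 1e-4, seed = 1, top_fraction = 0.001,
                        law = "normal") {
  models <- em_fit(x, K = K, n_runs = n_runs, max_iter = max_iter,
                   tol = tol, seed = seed)
  cf <- cluster_freqs_by_pop(models, x)
  if (is.null(kin)) {
    ds_freqs <- if (inherits(x, "genotype_dataset")) pop_allele_freqs(x)
                else hap_pop_freqs(x)
    kin <- build_kinship(reynolds_distance(ds_freqs))
  }
  hf <- hapflk(cf, kin)
  st <- standardize(hf$raw, law = law, top_fraction = top_fraction)
  snps <- cf$snps
  per_snp <- data.frame(snp = hf$snp,
                        chrom = if (!is.null(snps)) snps$chrom else 1L,
                        bp = if (!is.null(snps)) snps$bp else hf$snp,
                        raw = hf$raw, z = st$z, pvalue = st$pvalue,
                        flagged = st$flagged)
  sig <- per_snp[per_snp$flagged, , drop = FALSE]
  regions <- if (nrow(sig)) {
    win <- data.frame(chrom = sig$chrom, first_snp = sig$snp,
                      last_snp = sig$snp, start_bp = sig$bp,
                      end_bp = sig$bp, stat = sig$raw, n_defined = 1)
    windows_to_regions(win, method = "hapFLK")
  } else windows_to_regions(sig[0, 0], method = "hapFLK")
  list(models = models, cluster_freqs = cf, kinship = kin,
       per_snp = per_snp, regions = regions, threshold = st$threshold)
}
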