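# Genomic relationship matrix and principal component analysis of
# population stratification.

#' Genomic relationship matrix
#'
#' VanRaden-style GRM between samples. Missing calls are mean-imputed per
#' SNP; monomorphic SNPs carry no information and are skipped (the averaging
#' denominator shrinks accordingly).
#'
#' \code{standardized}: \eqn{G_{ij} = \frac{1}{M}\sum_l
#' \frac{(x_{il}-2p_l)(x_{jl}-2p_l)}{2p_l(1-p_l)}}.
#' \code{centered}: the same without the per-SNP variance scaling (and with
#' denominator \eqn{M}).
#'
#' @param ds a \code{genotype_dataset}.
#' @param method \code{"standardized"} (default) or \code{"centered"}.
#' @return symmetric samples x samples matrix.
#' @export
grm <- function(ds, method = c("standardized", "centered")) {
  method <- match.arg(method)
  x <- ds$calls
  p <- allele_freq(ds)
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM undefined")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  mu <- matrix(2 * p, nrow(x), ncol(x), byrow = TRUE)
  z <- x - mu
  z[is.na(z)] <- 0  # mean imputation: imputed dosage is 2p, centered to 0
  if (method == "standardized")
    z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  g <- tcrossprod(z) / ncol(z)
  dimnames(g) <- list(ds$samples$id, ds$samples$id)
  g
}

#' PCA of a genomic relationship matrix
#'
#' Eigendecomposition of the double-centered GRM. Component scores are
#' eigenvectors scaled by the square root of their eigenvalues; variance
#' explained is each nonnegative eigenvalue as a percentage of their sum.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param g symmetric matrix from \code{\link{grm}}.
#' @param k number of components to return (truncated to the count of
#'   positive eigenvalues, with a warning).
#' @return object of class \code{pca_result}: list with \code{scores}
#'   (samples x k), \code{variance_explained} (percent, length k) and
#'   \code{values} (all nonnegative eigenvalues).
#' @export
pca <- function(g, k = 10) {
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  if (max(abs(g - t(g))) > 1e-8) stop("GRM must be symmetric")
  n <- nrow(g)
  cm <- diag(n) - matrix(1 / n, n, n)
  gc <- cm %*% g %*% cm
  e <- eigen((gc + t(gc)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  vals <- e$values[pos]
  if (k > length(vals)) {
    warning("k = ", k, " exceeds rank ", length(vals), "; truncating")
    k <- length(vals)
  }
  vec <- e$vectors[, which(pos)[seq_len(k)], drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(vals[seq_len(k)]), "*")
  rownames(scores) <- rownames(g)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 variance_explained = 100 * vals[seq_len(k)] / sum(vals),
                 values = vals),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  ve <- x$variance_explained
  cat("  variance explained (%):",
      paste(sprintf("%.2f", utils::head(ve, 5)), collapse = ", "),
      if (length(ve) > 5) "...", "\n")
  invisible(x)
}

#' Write PCA scores and variance table
#'
#' @param p a \code{pca_result}.
#' @param path output path for a tab-separated table (sample, PCs, with a
#'   final comment-free header row); variance explained is written to
#'   \code{paste0(path, ".var")}.
#' @param populations optional character vector of population labels to
#'   include as a column.
#' @return \code{path}, invisibly.
#' @export
write_pca <- function(p, path, populations = NULL) {
  tab <- data.frame(sample = rownames(p$scores) %||% seq_len(nrow(p$scores)),
                    p$scores, check.names = FALSE)
  if (!is.null(populations)) tab$population <- populations
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(component = colnames(p$scores),
               variance_explained_pct = p$variance_explained),
    paste0(path, ".var"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
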