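# fastPHASE-style localized haplotype-cluster model fitted by EM.
# Phased input uses the haploid hidden-Markov chain (states = clusters);
# unphased genotypes use the product chain over ordered cluster pairs with
# genotype emissions summing over phase.

.theta_clamp <- c(1e-4, 1 - 1e-4)

.as_chain_input <- function(x) {
  # returns list(X = L x n_chains integer matrix (-1 missing),
  #              mode, pop = 0-based chain population index, pops = levels)
  if (inherits(x, "genotype_dataset")) {
    X <- t(x$calls)
    X[is.na(X)] <- -1L
    pops <- sort(unique(x$samples$population))
    pop <- match(x$samples$population, pops) - 1L
    list(X = X, mode = "genotype", pop = as.integer(pop), pops = pops,
         snps = x$snps, n_chains_per_unit = 1L)
  } else if (inherits(x, "haplotype_set")) {
    X <- t(x$haps)
    X[is.na(X)] <- -1L
    pops <- sort(unique(x$hap_population))
    pop <- match(x$hap_population, pops) - 1L
    list(X = X, mode = "haploid", pop = as.integer(pop), pops = pops,
         snps = x$snps, n_chains_per_unit = 1L)
  } else if (is.matrix(x)) {
    X <- t(x)
    X[is.na(X)] <- -1L
    if (any(X > 1L)) stop("haplotype matrices must be 0/1; use a ",
                          "genotype_dataset for unphased dosages")
    list(X = X, mode = "haploid", pop = rep(0L, nrow(x)), pops = "pooled",
         snps = NULL, n_chains_per_unit = 1L)
  } else stop("x must be a genotype_dataset, haplotype_set, or 0/1 matrix")
}

.init_model <- function(ci, K, seed) {
  set.seed(seed)
  L <- nrow(ci$X)
  # pooled allele-2 frequency per site over chains
  obs <- ci$X >= 0
  tot <- rowSums(ifelse(obs, ci$X, 0L))
  cnt <- rowSums(obs) * (if (ci$mode == "genotype") 2 else 1)
  pfreq <- ifelse(cnt > 0, tot / cnt, 0.5)
  alpha <- matrix(stats::rgamma(L * K, shape = 2), L, K)
  alpha <- alpha / rowSums(alpha)
  theta <- matrix(pfreq, L, K) + matrix(stats::rnorm(L * K, 0, 0.1), L, K)
  theta <- pmin(pmax(theta, .theta_clamp[1]), .theta_clamp[2])
  if (L > 1) {
    if (!is.null(ci$snps) && !is.null(ci$snps$cm) && any(diff(ci$snps$cm) > 0)) {
      dd <- pmax(diff(ci$snps$cm), 0)
      dd[ci$snps$chrom[-1] != ci$snps$chrom[-L]] <- 50  # chromosome break
      rho <- 1 - exp(-dd)
      rho[rho <= 0] <- 0.02
    } else {
      rho <- rep(0.02, L - 1)
    }
  } else rho <- numeric(0)
  list(alpha = alpha, rho = rho, theta = theta)
}

.run_estep <- function(ci, alpha, rho, theta, n_pop, want_stats) {
  fn <- if (ci$mode == "haploid") .hap_estep_cpp else .dip_estep_cpp
  fn(ci$X, alpha, as.numeric(rho), theta, ci$pop, n_pop, want_stats)
}

#' Fit the haplotype-cluster model by EM
#'
#' Fits \code{n_runs} independent EM runs (run \code{i} is seeded with
#' \code{seed + i - 1}) of the K-cluster mosaic model on the pooled sample.
#' Parameters: \code{alpha} (per-SNP cluster weights, also the jump
#' destination law), \code{rho} (per-interval jump probability, shared
#' across clusters), \code{theta_emit} (per-SNP, per-cluster allele-2
#' emission frequency, clamped to [1e-4, 1-1e-4]). Each run iterates EM
#' until the log-likelihood improves by less than \code{tol} or
#' \code{max_iter} is reached; the trace is non-decreasing by the EM
#' guarantee.
#'
#' @param x a \code{genotype_dataset} (unphased: ordered-pair chain), a
#'   \code{haplotype_set} from \code{\link{simulate_haplotypes}}, or a
#'   0/1 haplotype matrix (rows = haplotypes).
#' @param K number of haplotype clusters (default 10).
#' @param n_runs number of EM restarts (default 20).
#' @param max_iter maximum EM iterations per run (default 100).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param seed integer seed of the first run.
#' @return list of \code{cluster_model} objects, one per run.
#' @export
em_fit <- function(x, K = 10, n_runs = 20, max_iter = 100, tol = 1e-4,
                   seed = 1) {
  if (K < 1) stop("K must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  ci <- .as_chain_input(x)
  n_pop <- length(ci$pops)
  n_chains <- ncol(ci$X) * (if (ci$mode == "genotype") 2L else 1L)
  lapply(seq_len(n_runs), function(run) {
    par <- .init_model(ci, K, seed + run - 1L)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      es <- .run_estep(ci, par$alpha, par$rho, par$theta, n_pop, TRUE)
      if (!is.finite(es$loglik))
        stop("EM run ", run, " aborted: non-finite log-likelihood at ",
             "iteration ", it)
      trace <- c(trace, es$loglik)
      conv <- it > 1 && (trace[it] - trace[it - 1]) < tol
      if (conv) break
      # M-step
      par$alpha[1, ] <- es$init_occ / sum(es$init_occ)
      if (nrow(par$alpha) > 1) {
        upd <- es$jump_tot > 1e-12
        if (any(upd))
          par$alpha[which(upd) + 1L, ] <-
            es$jump_dest[upd, , drop = FALSE] / es$jump_tot[upd]
        par$rho <- pmin(pmax(es$jump_tot / n_chains, 1e-6), 1 - 1e-6)
      }
      den_ok <- es$emit_den > 1e-12
      th <- par$theta
      th[den_ok] <- es$emit_num[den_ok] / es$emit_den[den_ok]
      par$theta <- pmin(pmax(th, .theta_clamp[1]), .theta_clamp[2])
    }
    structure(list(K = as.integer(K), alpha = par$alpha, rho = par$rho,
                   theta_emit = par$theta, loglik = trace,
                   seed = seed + run - 1L, mode = ci$mode,
                   populations = ci$pops),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: K =", x$K, ", L =", nrow(x$alpha), "SNPs, mode =",
      x$mode, "\n")
  cat(sprintf("  loglik %.3f after %d EM iterations (seed %d)\n",
              utils::tail(x$loglik, 1), length(x$loglik), x$seed))
  invisible(x)
}

#' Posterior cluster memberships for one sequence
#'
#' Scaled forward-backward inference under a fitted model. For a haploid
#' sequence the result is the per-SNP posterior over the K clusters; for an
#' unphased genotype row it is the mean of the two chains' marginal
#' posteriors (still summing to 1 per SNP). Missing calls are marginalized
#' out of the emission.
#'
#' @param model a \code{cluster_model}.
#' @param sequence integer vector of length L: 0/1 (haplotype) or 0/1/2
#'   (genotype), \code{NA} = missing.
#' @param type \code{"auto"} (use the model's mode), \code{"haplotype"} or
#'   \code{"genotype"}.
#' @return list with \code{posterior} (L x K matrix, rows sum to 1) and
#'   \code{loglik}.
#' @export
forward_backward <- function(model, sequence,
                             type = c("auto", "haplotype", "genotype")) {
  type <- match.arg(type)
  if (type == "auto")
    type <- if (model$mode == "haploid") "haplotype" else "genotype"
  L <- nrow(model$alpha)
  if (length(sequence) != L)
    stop("sequence length ", length(sequence), " != model length ", L)
  X <- matrix(as.integer(sequence), L, 1)
  X[is.na(X)] <- -1L
  fn <- if (type == "haplotype") .hap_estep_cpp else .dip_estep_cpp
  es <- fn(X, model$alpha, as.numeric(model$rho), model$theta_emit,
           0L, 1L, FALSE)
  post <- es$pop_gamma[, , 1, drop = TRUE]
  post <- matrix(post, L, model$K)
  post <- post / rowSums(post)
  list(posterior = post, loglik = es$loglik)
}

#' Log-likelihood of data under a fitted model
#'
#' @param model a \code{cluster_model}.
#' @param x input as in \code{\link{em_fit}} (must match the model's mode).
#' @return total log-likelihood.
#' @export
model_loglik <- function(model, x) {
  ci <- .as_chain_input(x)
  if (ci$mode != model$mode)
    stop("input mode (", ci$mode, ") differs from model mode (",
         model$mode, ")")
  es <- .run_estep(ci, model$alpha, model$rho, model$theta_emit,
                   length(ci$pops), FALSE)
  es$loglik
}

#' Per-population cluster frequencies
#'
#' For each EM run, population p's frequency of cluster k at SNP l is the
#' average posterior membership over p's chains (each diploid contributes
#' two chains). This is the quantity hapFLK differentiates.
#'
#' @param models list of \code{cluster_model} from \code{\link{em_fit}}.
#' @param x the input the models were fitted on.
#' @return object of class \code{cluster_freqs}: list with \code{freqs}
#'   (list over runs of L x K x P arrays), \code{populations},
#'   \code{n_runs}, \code{K}, \code{snps}.
#' @export
cluster_freqs_by_pop <- function(models, x) {
  ci <- .as_chain_input(x)
  pops <- ci$pops
  counts <- tabulate(ci$pop + 1L, nbins = length(pops)) *
    (if (ci$mode == "genotype") 2 else 1)
  if (any(counts == 0)) stop("population with 0 samples: ",
                             paste(pops[counts == 0], collapse = ", "))
  freqs <- lapply(models, function(m) {
    stopifnot(inherits(m, "cluster_model"))
    es <- .run_estep(ci, m$alpha, m$rho, m$theta_emit, length(pops), FALSE)
    arr <- es$pop_gamma
    for (p in seq_along(pops)) arr[, , p] <- arr[, , p] / counts[p]
    arr
  })
  structure(list(freqs = freqs, populations = pops,
                 n_runs = length(models), K = models[[1]]$K,
                 snps = ci$snps),
            class = "cluster_freqs")
}

#' Export cluster frequencies as a long table
#'
#' @param cf a \code{cluster_freqs}.
#' @param path output path; tab-separated columns run, population, snp,
#'   cluster, frequency.
#' @return \code{path}, invisibly.
#' @export
write_cluster_freqs <- function(cf, path) {
  rows <- list()
  for (r in seq_len(cf$n_runs)) {
    a <- cf$freqs[[r]]
    for (p in seq_along(cf$populations)) {
      mat <- a[, , p, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, population = cf$populations[p],
        snp = rep(seq_len(dim(a)[1]), times = dim(a)[2]),
        cluster = rep(seq_len(dim(a)[2]), each = dim(a)[1]),
        frequency = as.vector(mat))
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
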