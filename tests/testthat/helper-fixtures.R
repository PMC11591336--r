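# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# quick dataset from a calls matrix (samples x SNPs)
make_ds <- function(calls, chrom = NULL, bp = NULL, populations = NULL,
                    groups = NULL, allele1 = "A", allele2 = "B") {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) bp <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  if (is.null(populations)) populations <- rep("pop1", n)
  if (is.null(groups)) groups <- rep("unassigned", n)
  genotype_dataset(
    calls,
    samples = data.frame(id = sprintf("s%03d", seq_len(n)),
                         family = "f", population = populations,
                         group = groups, stringsAsFactors = FALSE),
    snps = data.frame(chrom = chrom, id = sprintf("snp%04d", seq_len(m)),
                      cm = bp / 1e6, bp = bp,
                      allele1 = rep_len(allele1, m),
                      allele2 = rep_len(allele2, m),
                      stringsAsFactors = FALSE))
}

# random dataset with no monomorphic SNPs and moderate missingness
random_ds <- function(n = 20, m = 50, miss = 0, seed = 1) {
  set.seed(seed)
  repeat {
    p <- runif(m, 0.2, 0.8)
    calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
    if (miss > 0) calls[matrix(runif(n * m) < miss, n, m)] <- NA
    freq <- colMeans(calls, na.rm = TRUE) / 2
    if (all(is.finite(freq) & freq > 0 & freq < 1)) break
  }
  make_ds(calls)
}

# straight-from-formula Weir-Cockerham oracle for a single SNP
wc_oracle_snp <- function(geno, grp) {
  lev <- sort(unique(grp[!is.na(geno) | TRUE]))
  lev <- lev[!is.na(lev)]
  r <- length(lev)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    g <- geno[grp == lev[k] & !is.na(grp)]
    g <- g[!is.na(g)]
    n_i[k] <- length(g)
    p_i[k] <- sum(g) / (2 * length(g))
    h_i[k] <- mean(g == 1)
  }
  if (any(n_i == 0)) return(c(a = NA, b = NA, c = NA, theta = NA))
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  th <- if (a + b + cc == 0) NA else a / (a + b + cc)
  c(a = a, b = b, c = cc, theta = th)
}

# brute-force haploid HMM likelihood/posterior by full path enumeration
hap_enumerate <- function(x, alpha, rho, theta) {
  L <- length(x); K <- ncol(alpha)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  emis <- function(l, k) {
    if (is.na(x[l])) 1
    else if (x[l] == 1) theta[l, k]
    else 1 - theta[l, k]
  }
  probs <- apply(paths, 1, function(pp) {
    pr <- alpha[1, pp[1]] * emis(1, pp[1])
    for (l in 2:L) {
      tr <- (1 - rho[l - 1]) * (pp[l] == pp[l - 1]) +
        rho[l - 1] * alpha[l, pp[l]]
      pr <- pr * tr * emis(l, pp[l])
    }
    pr
  })
  lik <- sum(probs)
  post <- matrix(0, L, K)
  for (l in seq_len(L)) for (k in seq_len(K))
    post[l, k] <- sum(probs[paths[, l] == k]) / lik
  list(lik = lik, loglik = log(lik), posterior = post)
}

# published region coordinate fixtures (kb spans from a sheep prolificacy
# selection scan), used to exercise the cross-method intersection logic
published_fst_regions <- function() {
  read_regions_fixture(system.file("extdata", "fst_regions_published.tsv",
                                   package = "sweepscan"))
}
published_hapflk_regions <- function() {
  read_regions_fixture(system.file("extdata", "hapflk_regions_published.tsv",
                                   package = "sweepscan"))
}
read_regions_fixture <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(chrom = tab$chrom, start_bp = tab$start_kb * 1000,
             end_bp = tab$end_kb * 1000, stat = 0,
             method = tab$method, stringsAsFactors = FALSE)
}
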