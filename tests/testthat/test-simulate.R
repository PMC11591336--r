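# The synthetic-data generator: drift law, founder-mosaic LD, sweep
# injection and emission.

test_that("identical configurations give bit-identical output", {
  cfg <- sim_config(n_diploids = c(low1 = 5, low2 = 5, low3 = 5, high = 5),
                    n_chromosomes = 2, n_snps_per_chrom = 100,
                    missing_rate = 0.05,
                    sweeps = list(list(population = "high", chrom = 1,
                                       start_snp = 40, end_snp = 59,
                                       s = 0.9)),
                    seed = 55)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$calls, b$dataset$calls)
  expect_identical(a$hapset$haps, b$hapset$haps)
  expect_identical(a$freqs, b$freqs)
})

test_that("vanishing drift leaves tip frequencies at the ancestral values", {
  cfg <- sim_config(tree = star_tree(paste0("p", 1:4), c = 1e-6),
                    n_diploids = stats::setNames(rep(2, 4), paste0("p", 1:4)),
                    n_chromosomes = 1, n_snps_per_chrom = 2000, seed = 3)
  fr <- simulate_frequencies(cfg)
  rms <- sqrt(mean((sweep(fr$tips, 2, fr$ancestral))^2))
  expect_lt(rms, 0.01)
})

test_that("star-tree drift matches the Balding-Nichols moment", {
  cfg <- sim_config(tree = star_tree(paste0("p", 1:4), c = 0.05),
                    n_diploids = stats::setNames(rep(2, 4), paste0("p", 1:4)),
                    n_chromosomes = 1, n_snps_per_chrom = 5000, seed = 21)
  fr <- simulate_frequencies(cfg)
  # across-SNP average of Var(p_i)/p(1-p) estimates c
  anc <- fr$ancestral
  v <- apply(fr$tips, 2, var)
  est <- mean(v / (anc * (1 - anc)))
  expect_lt(abs(est - 0.05), 0.01)
})

test_that("sibling tips under a long shared branch are highly correlated", {
  tree <- list(c = 0, children = list(
    list(c = 0.2, children = list(list(c = 1e-4, pop = "s1"),
                                  list(c = 1e-4, pop = "s2"))),
    list(c = 0.05, pop = "out")))
  cfg <- sim_config(tree = tree,
                    n_diploids = c(s1 = 2, s2 = 2, out = 2),
                    n_chromosomes = 1, n_snps_per_chrom = 3000, seed = 9)
  fr <- simulate_frequencies(cfg)
  expect_gt(cor(fr$tips["s1", ], fr$tips["s2", ]), 0.9)
})

test_that("switch rate controls founder copying and LD decay", {
  base <- function(sw, seed) {
    cfg <- sim_config(tree = star_tree("p1", 0.05),
                      n_diploids = c(p1 = 30), n_chromosomes = 1,
                      n_snps_per_chrom = 400, n_founders = 10,
                      switch_rate = sw, seed = seed)
    list(cfg = cfg, sim = simulate_haplotypes(cfg, simulate_frequencies(cfg)))
  }
  # rate 0: every haplotype is an exact founder copy
  z <- base(0, 2)
  fd <- z$sim$truth$founders$p1
  for (i in 1:10) {
    h <- z$sim$haps[i, ]
    expect_true(any(apply(fd, 1, function(f) all(f == h))))
  }
  # rate 1 with many founders: adjacent-SNP LD near zero
  cfg1 <- sim_config(tree = star_tree("p1", 0.05), n_diploids = c(p1 = 200),
                     n_chromosomes = 1, n_snps_per_chrom = 300,
                     n_founders = 500, switch_rate = 1, seed = 4)
  hs1 <- simulate_haplotypes(cfg1, simulate_frequencies(cfg1))
  r2 <- sapply(seq_len(299), function(l)
    suppressWarnings(cor(hs1$haps[, l], hs1$haps[, l + 1])^2))
  expect_lt(mean(r2, na.rm = TRUE), 0.05)
  # default rates: r2 decays with distance (negative rank correlation)
  cfg2 <- sim_config(tree = star_tree("p1", 0.05), n_diploids = c(p1 = 150),
                     n_chromosomes = 1, n_snps_per_chrom = 300,
                     n_founders = 20, switch_rate = 0.05, seed = 6)
  hs2 <- simulate_haplotypes(cfg2, simulate_frequencies(cfg2))
  gaps <- c(1, 2, 4, 8, 16, 32, 64)
  mean_r2 <- sapply(gaps, function(g) {
    vals <- sapply(seq_len(300 - g), function(l)
      suppressWarnings(cor(hs2$haps[, l], hs2$haps[, l + g])^2))
    mean(vals, na.rm = TRUE)
  })
  expect_lt(cor(gaps, mean_r2, method = "spearman"), 0)
  expect_gt(mean_r2[1], mean_r2[length(gaps)])
})

test_that("sweep injection reaches the target and is local and idempotent", {
  cfg <- sim_config(n_diploids = c(low1 = 20, low2 = 20, low3 = 20,
                                   high = 20),
                    n_chromosomes = 2, n_snps_per_chrom = 300,
                    sweeps = list(list(population = "high", chrom = 1,
                                       start_snp = 100, end_snp = 119,
                                       s = 0.9)),
                    seed = 77)
  fr <- simulate_frequencies(cfg)
  hs0 <- simulate_haplotypes(cfg, fr)
  hs1 <- inject_sweep(hs0, cfg$sweeps[[1]], cfg, 1)
  sw <- hs1$truth$sweeps[[1]]
  rows <- which(hs1$hap_population == "high")
  seg <- hs1$truth$founders$high[sw$founder, sw$snp_index]
  carriers <- apply(hs1$haps[rows, sw$snp_index, drop = FALSE], 1,
                    function(h) all(h == seg))
  expect_gte(mean(carriers), 0.9)
  # other populations and out-of-span sites untouched
  other <- which(hs1$hap_population != "high")
  expect_identical(hs1$haps[other, ], hs0$haps[other, ])
  outside <- setdiff(seq_len(ncol(hs1$haps)), sw$snp_index)
  expect_identical(hs1$haps[rows, outside], hs0$haps[rows, outside])
  # idempotent at the target
  hs2 <- inject_sweep(hs1, cfg$sweeps[[1]], cfg, 1)
  expect_identical(hs2$haps, hs1$haps)
})

test_that("the injected sweep dominates the genome-wide theta background", {
  cfg <- sim_config(n_diploids = c(low1 = 25, low2 = 25, low3 = 25,
                                   high = 25),
                    n_chromosomes = 1, n_snps_per_chrom = 1000,
                    sweeps = list(list(population = "high", chrom = 1,
                                       start_snp = 500, end_snp = 519,
                                       s = 0.9)),
                    seed = 5)
  sim <- simulate_dataset(cfg)
  th <- wc_theta_per_snp(sim$dataset)
  span <- sim$truth$sweeps[[1]]$snp_index
  span_mean <- mean(th$theta[span], na.rm = TRUE)
  genome_mean <- mean(th$theta[th$defined], na.rm = TRUE)
  expect_gt(span_mean, 5 * genome_mean)
})

test_that("emission applies missingness at the configured rate and round-trips", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_diploids = c(low1 = 30, low2 = 30, low3 = 30,
                                   high = 35),
                    n_chromosomes = 1, n_snps_per_chrom = 800,
                    missing_rate = 0.1, seed = 12)
  sim <- simulate_dataset(cfg)
  expect_equal(mean(is.na(sim$dataset$calls)), 0.1, tolerance = 0.01)
  # rate 0: full call rate
  ds0 <- emit_dataset(sim$hapset, cfg, missing_rate = 0)
  expect_equal(sum(is.na(ds0$calls)), 0)
  # PLINK round trip of the emitted dataset
  prefix <- file.path(dir, "sim")
  write_plink(sim$dataset, prefix, "binary")
  back <- read_plink(prefix, format = "binary")
  expect_identical(back$calls, sim$dataset$calls)
})

test_that("a neutral scan flags only the expected number of windows, spread over chromosomes", {
  cfg <- sim_config(n_diploids = c(low1 = 20, low2 = 20, low3 = 20,
                                   high = 20),
                    n_chromosomes = 5, n_snps_per_chrom = 600, seed = 13)
  sim <- simulate_dataset(cfg)
  res <- fst_scan(sim$dataset, scan_config(top_fraction = 0.001))
  n_exp <- ceiling(0.001 * nrow(res$windows))
  expect_gte(res$significant |> nrow(), n_exp)
  # ties aside, the count stays near the target
  expect_lte(nrow(res$significant), n_exp + 5)
  # window positions roughly uniform across chromosomes
  tab <- table(factor(res$windows$chrom, levels = 1:5))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})
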