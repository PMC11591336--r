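# Haplotype-cluster model: forward-backward correctness against exhaustive
# path enumeration, EM behavior, and per-population cluster frequencies.

small_model <- function(K = 3, L = 6, seed = 17) {
  set.seed(seed)
  alpha <- matrix(rgamma(L * K, 2), L, K)
  alpha <- alpha / rowSums(alpha)
  structure(list(K = K, alpha = alpha, rho = runif(L - 1, 0.05, 0.6),
                 theta_emit = matrix(runif(L * K, 0.05, 0.95), L, K),
                 loglik = numeric(0), seed = seed, mode = "haploid",
                 populations = "pooled"),
            class = "cluster_model")
}

test_that("haploid forward-backward matches exhaustive path enumeration", {
  m <- small_model()
  for (x in list(c(0, 1, 1, 0, 1, 0), c(1, NA, 0, 1, NA, 1))) {
    fb <- forward_backward(m, x, type = "haplotype")
    ref <- hap_enumerate(x, m$alpha, m$rho, m$theta_emit)
    expect_equal(fb$loglik, ref$loglik, tolerance = 1e-10)
    expect_lt(max(abs(fb$posterior - ref$posterior)), 1e-10)
  }
})

test_that("genotype chain likelihood of a homozygous sample squares the haploid one", {
  m <- small_model(seed = 23)
  hap <- c(1, 0, 1, 1, 0, 1)
  mg <- m; mg$mode <- "genotype"
  fb_h <- forward_backward(m, hap, type = "haplotype")
  fb_g <- forward_backward(mg, 2 * hap, type = "genotype")
  expect_equal(fb_g$loglik, 2 * fb_h$loglik, tolerance = 1e-8)
  # and the chain-marginal posterior matches the haploid posterior
  expect_lt(max(abs(fb_g$posterior - fb_h$posterior)), 1e-8)
})

test_that("genotype chain forward-backward matches enumeration over phased pairs", {
  m <- small_model(K = 2, L = 5, seed = 29)
  g <- c(1, 2, 0, 1, NA)
  mg <- m; mg$mode <- "genotype"
  fb <- forward_backward(mg, g, type = "genotype")
  # enumerate over all compatible ordered haplotype pairs
  combos <- expand.grid(rep(list(0:1), 2 * 5))
  lik <- 0
  post <- matrix(0, 5, 2)
  for (i in seq_len(nrow(combos))) {
    h1 <- as.numeric(combos[i, 1:5]); h2 <- as.numeric(combos[i, 6:10])
    ok <- all(is.na(g) | (h1 + h2) == g)
    if (!ok) next
    e1 <- hap_enumerate(h1, m$alpha, m$rho, m$theta_emit)
    e2 <- hap_enumerate(h2, m$alpha, m$rho, m$theta_emit)
    lik <- lik + e1$lik * e2$lik
    post <- post + e1$lik * e2$lik * (e1$posterior + e2$posterior) / 2
  }
  expect_equal(fb$loglik, log(lik), tolerance = 1e-8)
  expect_lt(max(abs(fb$posterior - post / lik)), 1e-8)
})

test_that("K = 1 collapses to site independence", {
  set.seed(3)
  haps <- matrix(rbinom(40 * 12, 1, rep(runif(12, 0.2, 0.8), each = 40)),
                 40, 12)
  mods <- em_fit(haps, K = 1, n_runs = 1, max_iter = 20, seed = 5)
  m <- mods[[1]]
  p <- colMeans(haps)
  expect_equal(as.vector(m$theta_emit), p, tolerance = 1e-8)
  ll_binom <- sum(haps %*% diag(log(p)) + (1 - haps) %*% diag(log(1 - p)))
  expect_equal(utils::tail(m$loglik, 1), ll_binom, tolerance = 1e-6)
  fb <- forward_backward(m, haps[1, ])
  expect_equal(as.vector(fb$posterior), rep(1, 12))
})

test_that("rho = 0 with uniform weights reduces to a static mixture", {
  m <- small_model(K = 3, L = 6, seed = 41)
  m$rho <- rep(0, 5)
  m$alpha <- matrix(1 / 3, 6, 3)
  x <- c(1, 0, 1, 1, 0, 0)
  fb <- forward_backward(m, x, type = "haplotype")
  lik_k <- vapply(1:3, function(k)
    prod(ifelse(x == 1, m$theta_emit[, k], 1 - m$theta_emit[, k])), 0)
  resp <- lik_k / sum(lik_k)
  for (l in 1:6) expect_equal(fb$posterior[l, ], resp, tolerance = 1e-10)
})

test_that("EM log-likelihood traces are monotone and seeded runs reproduce", {
  set.seed(11)
  cfg <- sim_config(n_diploids = c(low1 = 8, low2 = 8, low3 = 8, high = 8),
                    n_chromosomes = 1, n_snps_per_chrom = 120, seed = 19)
  sim <- simulate_dataset(cfg)
  mods <- em_fit(sim$hapset, K = 4, n_runs = 3, max_iter = 15, seed = 7)
  for (m in mods) expect_true(all(diff(m$loglik) > -1e-6))
  mods2 <- em_fit(sim$hapset, K = 4, n_runs = 3, max_iter = 15, seed = 7)
  expect_identical(lapply(mods, `[`, c("alpha", "rho", "theta_emit",
                                       "loglik")),
                   lapply(mods2, `[`, c("alpha", "rho", "theta_emit",
                                        "loglik")))
  # unphased fit on the emitted genotypes is monotone too
  modg <- em_fit(sim$dataset, K = 3, n_runs = 1, max_iter = 8, seed = 7)
  expect_true(all(diff(modg[[1]]$loglik) > -1e-6))
})

test_that("fit recovers a planted 3-cluster mosaic", {
  # generating model: 3 well-separated emission profiles, slow jumps
  set.seed(7)
  L <- 200; K <- 3; N <- 120
  theta_true <- matrix(runif(L * K), L, K)
  theta_true <- (theta_true > 0.5) * 0.95 + 0.025
  states <- matrix(0L, N, L)
  haps <- matrix(0L, N, L)
  for (i in seq_len(N)) {
    s <- sample.int(K, 1)
    for (l in seq_len(L)) {
      if (l > 1 && runif(1) < 0.03) s <- sample.int(K, 1)
      states[i, l] <- s
      haps[i, l] <- rbinom(1, 1, theta_true[l, s])
    }
  }
  mods <- em_fit(haps, K = 3, n_runs = 2, max_iter = 40, seed = 7)
  best <- mods[[which.max(vapply(mods, function(m) utils::tail(m$loglik, 1),
                                 0))]]
  # loglik reaches at least the generating model's (within 1%)
  gen <- structure(list(K = 3, alpha = matrix(1 / 3, L, 3),
                        rho = rep(0.03, L - 1), theta_emit = theta_true,
                        loglik = numeric(0), seed = 0, mode = "haploid",
                        populations = "pooled"), class = "cluster_model")
  ll_gen <- model_loglik(gen, haps)
  expect_gt(utils::tail(best$loglik, 1), ll_gen - abs(ll_gen) * 0.01)
  # posterior decode recovers the mosaic partition: cluster labels are only
  # locally identifiable, so score per-site co-assignment (Rand) agreement
  decode <- matrix(0L, N, L)
  for (i in seq_len(N))
    decode[i, ] <- max.col(forward_backward(best, haps[i, ])$posterior)
  rand <- vapply(seq_len(L), function(l) {
    same_t <- outer(states[, l], states[, l], "==")
    same_d <- outer(decode[, l], decode[, l], "==")
    mean(same_t[upper.tri(same_t)] == same_d[upper.tri(same_d)])
  }, 0)
  expect_gt(mean(rand), 0.8)
})

test_that("cluster frequencies by population sum to 1 and respect symmetry", {
  set.seed(2)
  haps <- matrix(rbinom(40 * 60, 1, 0.4), 40, 60)
  hs <- structure(list(haps = rbind(haps, haps),
                       hap_population = rep(c("a", "b"), each = 40),
                       hap_sample = rep(1:40, 2),
                       samples = NULL, snps = NULL, truth = NULL),
                  class = "haplotype_set")
  mods <- em_fit(hs, K = 3, n_runs = 1, max_iter = 10, seed = 9)
  cf <- cluster_freqs_by_pop(mods, hs)
  sums <- apply(cf$freqs[[1]], c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-8)
  # identical populations have identical frequency profiles
  expect_lt(max(abs(cf$freqs[[1]][, , 1] - cf$freqs[[1]][, , 2])), 1e-10)
})

test_that("a cluster fixed in one population is recovered in its frequencies", {
  set.seed(3)
  L <- 80
  # pop2 haplotypes share one distinctive haplotype over SNPs 30-50
  base <- matrix(rbinom(60 * L, 1, 0.5), 60, L)
  distinctive <- rbinom(L, 1, 0.5)
  pop <- rep(c("p1", "p2"), each = 30)
  region <- 30:50
  base[31:60, region] <- matrix(distinctive[region], 30, length(region),
                                byrow = TRUE)
  hs <- structure(list(haps = base, hap_population = pop,
                       hap_sample = seq_len(60), samples = NULL,
                       snps = NULL, truth = NULL),
                  class = "haplotype_set")
  mods <- em_fit(hs, K = 3, n_runs = 3, max_iter = 30, seed = 3)
  best <- which.max(vapply(mods, function(m) utils::tail(m$loglik, 1), 0))
  cf <- cluster_freqs_by_pop(mods[best], hs)
  f2 <- cf$freqs[[1]][region, , 2]   # pop2, in-region
  # some cluster carries the shared haplotype at high frequency in pop2
  expect_gt(max(colMeans(f2)), 0.9)
})
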