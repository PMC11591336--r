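# PLINK input/output, QC filters, KING relatedness, relatedness pruning and
# case/control grouping.

write_ped_fixture <- function(dir) {
  # 2 samples, 3 SNPs; dosages [[0,1,2],[2,NA,0]] relative to allele2
  writeLines(c("1\tB\t0.001\t1000", "1\tC\t0.002\t2000", "1\tD\t0.003\t3000"),
             file.path(dir, "fix.map"))
  writeLines(c(
    "f1\ts1\t0\t0\t0\t-9\tA\tA\tA\tG\tT\tT",
    "f2\ts2\t0\t0\t0\t-9\tG\tG\t0\t0\tC\tC"),
    file.path(dir, "fix.ped"))
  file.path(dir, "fix")
}

test_that("text reading transcribes a hand-written ped/map fixture", {
  dir <- withr::local_tempdir()
  ds <- read_plink(write_ped_fixture(dir), format = "text")
  expect_equal(dim_dataset(ds), c(2L, 3L))
  expect_equal(unname(ds$calls), rbind(c(0L, 1L, 2L), c(2L, NA, 0L)))
  expect_equal(ds$samples$id, c("s1", "s2"))
  expect_equal(ds$snps$bp, c(1000L, 2000L, 3000L))
  # allele1 = minor allele, ties broken lexicographically
  expect_equal(ds$snps$allele1, c("A", "A", "C"))
  expect_equal(ds$snps$allele2, c("G", "G", "T"))
})

test_that("text and binary round trips reproduce the dataset", {
  dir <- withr::local_tempdir()
  ds <- read_plink(write_ped_fixture(dir), format = "text")
  for (fmt in c("text", "binary")) {
    prefix <- file.path(dir, paste0("rt_", fmt))
    write_plink(ds, prefix, fmt)
    back <- read_plink(prefix, format = fmt)
    expect_equal(back$calls, ds$calls)
    expect_equal(back$snps, ds$snps)
    expect_equal(back$samples$id, ds$samples$id)
  }
})

test_that("non-autosomal SNPs are dropped with a reported count", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tA\t0\t1000", "27\tX1\t0\t2000", "2\tB\t0\t500"),
             file.path(dir, "x.map"))
  writeLines("f\ts1\t0\t0\t0\t-9\tA\tA\tG\tG\tT\tT", file.path(dir, "x.ped"))
  expect_message(ds <- read_plink(file.path(dir, "x"), format = "text"),
                 "dropped 1 non-autosomal")
  expect_equal(nrow(ds$snps), 2L)
  expect_equal(attr(ds, "n_dropped_nonautosomal"), 1L)
})

test_that("an empty dataset (0 SNPs) writes and re-reads", {
  dir <- withr::local_tempdir()
  ds <- make_ds(matrix(integer(0), 2, 0))
  for (fmt in c("text", "binary")) {
    prefix <- file.path(dir, paste0("empty_", fmt))
    write_plink(ds, prefix, fmt)
    back <- read_plink(prefix, format = fmt)
    expect_equal(dim_dataset(back), c(2L, 0L))
  }
})

test_that("random binary round trip is exact and write-read is idempotent for text", {
  dir <- withr::local_tempdir()
  ds <- random_ds(20, 50, miss = 0.1, seed = 7)
  write_plink(ds, file.path(dir, "bin"), "binary")
  back <- read_plink(file.path(dir, "bin"), format = "binary")
  expect_identical(back$calls, ds$calls)
  expect_equal(back$snps, ds$snps)
  # text carries no allele-role designation: write-read must be idempotent
  # on the image of read (allele roles inferred from counts)
  write_plink(ds, file.path(dir, "t1"), "text")
  d1 <- read_plink(file.path(dir, "t1"), format = "text")
  write_plink(d1, file.path(dir, "t2"), "text")
  d2 <- read_plink(file.path(dir, "t2"), format = "text")
  expect_identical(d2$calls, d1$calls)
  expect_equal(d2$snps, d1$snps)
})

test_that("binary -> text -> binary preserves the .bed payload after canonicalization", {
  dir <- withr::local_tempdir()
  ds <- random_ds(17, 40, miss = 0.05, seed = 3)
  canonicalize <- function(d) {
    flip <- d$snps$allele2 < d$snps$allele1
    d$calls[, flip] <- 2L - d$calls[, flip]
    tmp <- d$snps$allele1[flip]
    d$snps$allele1[flip] <- d$snps$allele2[flip]
    d$snps$allele2[flip] <- tmp
    d
  }
  write_plink(canonicalize(ds), file.path(dir, "a"), "binary")
  write_plink(ds, file.path(dir, "t"), "text")
  ds2 <- read_plink(file.path(dir, "t"), format = "text")
  write_plink(canonicalize(ds2), file.path(dir, "b"), "binary")
  expect_identical(readBin(file.path(dir, "a.bed"), "raw", 10000),
                   readBin(file.path(dir, "b.bed"), "raw", 10000))
})

test_that("qc_filter applies sample, call-rate and MAF rules with strict inequalities", {
  # one sample 10% missing at default thresholds
  calls <- matrix(1L, 5, 10)
  calls[1, 1] <- NA
  q <- qc_filter(make_ds(calls))
  expect_equal(q$report$n_samples_removed_missing, 1L)
  expect_equal(q$report$n_samples_output, 4L)

  # MAF 0.04 removed, 0.05 exactly retained (strict '<')
  set.seed(1)
  n <- 50
  c1 <- c(rep(1L, 4), rep(0L, n - 4))        # maf 4/100 = 0.04
  c2 <- c(rep(1L, 5), rep(0L, n - 5))        # maf 0.05
  c3 <- rbinom(n, 2, 0.5)
  q2 <- qc_filter(make_ds(cbind(c1, c2, c3)))
  expect_equal(q2$report$n_snps_removed_maf, 1L)
  expect_equal(q2$dataset$snps$id, c("snp0002", "snp0003"))

  # all samples removed is a hard error carrying the report
  allm <- matrix(NA_integer_, 3, 4)
  allm[, 1] <- 1L  # 75% missing each
  err <- tryCatch(qc_filter(make_ds(allm)), error = identity)
  expect_s3_class(err, "sweepscan_qc_error")
  expect_equal(err$report$n_samples_removed_missing, 3L)
})

test_that("qc_filter counts reconcile with an independent recount and it is idempotent", {
  ds <- random_ds(10, 100, miss = 0.06, seed = 11)
  q <- qc_filter(ds)
  # brute-force recount in filter order
  miss_s <- rowMeans(is.na(ds$calls))
  keep_s <- miss_s <= 0.05
  cr <- colMeans(!is.na(ds$calls[keep_s, , drop = FALSE]))
  keep_cr <- cr >= 0.95
  x <- ds$calls[keep_s, keep_cr, drop = FALSE]
  p <- colMeans(x, na.rm = TRUE) / 2
  keep_maf <- pmin(p, 1 - p) >= 0.05
  expect_equal(q$report$n_samples_removed_missing, sum(!keep_s))
  expect_equal(q$report$n_snps_removed_callrate, sum(!keep_cr))
  expect_equal(q$report$n_snps_removed_maf, sum(!keep_maf))
  expect_equal(dim(q$dataset$calls), c(sum(keep_s), sum(keep_maf)))
  # reconciliation identities
  r <- q$report
  expect_equal(r$n_snps_input - r$n_snps_removed_callrate -
                 r$n_snps_removed_maf, r$n_snps_output)
  expect_equal(r$n_samples_input - r$n_samples_removed_missing,
               r$n_samples_output)
  # idempotence
  q2 <- qc_filter(q$dataset)
  expect_equal(q2$dataset$calls, q$dataset$calls)
  expect_equal(q2$report$n_snps_removed_maf +
                 q2$report$n_snps_removed_callrate +
                 q2$report$n_samples_removed_missing, 0L)
})

test_that("KING kinship: duplicates give 0.5, opposite homozygotes are negative", {
  g <- c(0L, 1L, 2L, 1L, 0L, 1L)
  ds <- make_ds(rbind(g, g, 2L - g))
  phi <- king_kinship(ds)
  expect_equal(phi[1, 2], 0.5)
  expect_equal(diag(phi), rep(0.5, 3), ignore_attr = TRUE)
  expect_true(phi[1, 3] < 0)
  expect_equal(phi, t(phi))
})

test_that("KING kinship recovers parent-offspring relatedness", {
  set.seed(5)
  m <- 5000
  p <- runif(m, 0.2, 0.8)
  n_pairs <- 10
  phis <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    pa <- rbinom(m, 1, p) + rbinom(m, 1, p)       # parent genotype
    transmitted <- ifelse(pa == 1, rbinom(m, 1, 0.5), pa / 2)
    off <- transmitted + rbinom(m, 1, p)          # Mendelian drop
    phi <- king_kinship(make_ds(rbind(pa, off)))
    phis[i] <- phi[1, 2]
  }
  expect_lt(abs(mean(phis) - 0.25), 0.03)
})

test_that("KING kinship is invariant to SNP order and allele relabeling", {
  ds <- random_ds(8, 60, miss = 0.1, seed = 9)
  phi <- king_kinship(ds)
  perm <- sample(ncol(ds$calls))
  expect_equal(king_kinship(subset_dataset(ds, snps = perm)), phi)
  flip <- ds
  swap <- seq(1, 60, by = 3)
  flip$calls[, swap] <- 2L - flip$calls[, swap]
  expect_equal(king_kinship(flip), phi)
})

test_that("prune_related removes a minimal set", {
  ds <- random_ds(6, 30, seed = 2)
  # no pair above threshold: unchanged
  kin <- matrix(0, 6, 6); diag(kin) <- 0.5
  pr <- prune_related(ds, kin, threshold = 0.354)
  expect_equal(pr$dataset$calls, ds$calls)
  expect_length(pr$removed, 0)
  # one duplicate pair: exactly one removed
  kin2 <- kin; kin2[1, 2] <- kin2[2, 1] <- 0.5
  pr2 <- prune_related(ds, kin2, threshold = 0.354)
  expect_length(pr2$removed, 1)
  expect_true(pr2$removed %in% c("s001", "s002"))
})

test_that("greedy pruning matches exhaustive minimal removal on a planted clique", {
  set.seed(13)
  n <- 30
  ds <- random_ds(n, 30, seed = 13)
  kin <- matrix(runif(n * n, -0.1, 0.1), n, n)
  kin <- (kin + t(kin)) / 2
  clique <- c(4, 9, 17, 25)
  kin[clique, clique] <- 0.45
  diag(kin) <- 0.5
  thr <- 0.354
  pr <- prune_related(ds, kin, thr)
  # exhaustive search over removal subsets of the vertices carrying edges
  adj <- kin > thr; diag(adj) <- FALSE
  verts <- which(rowSums(adj) > 0)
  best <- length(verts)
  for (k in 0:length(verts)) {
    combs <- utils::combn(verts, k, simplify = FALSE)
    covered <- any(vapply(combs, function(rm) {
      keep <- setdiff(seq_len(n), rm)
      !any(adj[keep, keep])
    }, logical(1)))
    if (covered) { best <- k; break }
  }
  expect_equal(length(pr$removed), best)
  keep <- setdiff(seq_len(n), match(pr$removed, ds$samples$id))
  expect_false(any(adj[keep, keep]))
})

test_that("assign_groups applies the prolificacy thresholds", {
  ds <- random_ds(4, 10, seed = 1)
  phen <- c(s001 = 3, s002 = 7, s003 = 5, s999 = 4)
  expect_warning(ds2 <- assign_groups(ds, phen), "absent from dataset")
  expect_equal(ds2$samples$group,
               c("control", "case", "unassigned", "unassigned"))
})
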