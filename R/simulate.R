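# Synthetic multi-population SNP-array genotypes: Balding-Nichols drift
# along a population tree, founder-haplotype mosaics for LD, and injectable
# selective sweeps of known position. Provides known-truth inputs for every
# scan stage.

#' Population tree constructors
#'
#' A population tree is a nested list: each node has a drift parameter
#' \code{c} (Balding-Nichols divergence along the branch from its parent,
#' in (0,1); 0 at the root) and either \code{children} (a list of nodes) or
#' a \code{pop} tip label. \code{star_tree} puts every population at the
#' end of its own branch from the root; \code{default_sim_tree} emulates a
#' hierarchical design of three closely related populations (a shared
#' internal branch, then short tip branches) plus one diverged population.
#'
#' @param pops character vector of population names.
#' @param c drift parameter per branch.
#' @return a tree node list.
#' @export
star_tree <- function(pops, c = 0.05) {
  list(c = 0, children = lapply(pops, function(p) list(c = c, pop = p)))
}

#' @rdname star_tree
#' @param c_shared shared branch above the three related populations.
#' @param c_tip tip branches of the related populations.
#' @param c_diverged branch of the diverged (high) population.
#' @details Default branch drifts are calibrated so that, together with the
#'   founder-pool bottleneck, the realized between-group windowed F_ST sits
#'   near 0.05 — the differentiation level typical of the sheep-breed
#'   contrast this generator emulates.
#' @export
default_sim_tree <- function(c_shared = 0.02, c_tip = 0.015,
                             c_diverged = 0.03) {
  list(c = 0, children = list(
    list(c = c_shared, children = list(
      list(c = c_tip, pop = "low1"),
      list(c = c_tip, pop = "low2"),
      list(c = c_tip, pop = "low3"))),
    list(c = c_diverged, pop = "high")))
}

.tree_tips <- function(node) {
  if (!is.null(node$pop)) return(node$pop)
  unlist(lapply(node$children, .tree_tips))
}

#' Simulation configuration
#'
#' Defaults emulate the study design this simulator stands in for: four
#' populations (three related low-prolificacy, one diverged
#' high-prolificacy) genotyped at about 42k autosomal SNPs on 26
#' chromosomes with evenly spaced markers (50 kb, ~1 cM/Mb).
#'
#' @param tree population tree (see \code{\link{star_tree}}).
#' @param n_diploids named integer vector of diploids per population;
#'   names must match the tree's tips.
#' @param n_chromosomes,n_snps_per_chrom map dimensions.
#' @param ancestral_range range of the uniform ancestral-frequency law.
#' @param n_founders founder haplotypes per population (M); \code{Inf}
#'   draws every haplotype site-wise Bernoulli(tip frequency) instead
#'   (island model: no LD, no founder bottleneck drift). Finite pools add
#'   about 1/M of extra drift on top of the tree's branch parameters.
#' @param switch_rate per-interval probability that a sample haplotype
#'   switches founder (controls LD decay).
#' @param sweeps list of sweep specs, each
#'   \code{list(population, chrom, start_snp, end_snp, s)}: within the SNP
#'   span the modal founder haplotype is driven to frequency >= s in the
#'   target population.
#' @param missing_rate i.i.d. genotype missingness applied at emission.
#' @param case_populations populations labeled \code{case} (others are
#'   controls).
#' @param bp_spacing physical spacing between adjacent SNPs.
#' @param seed mandatory integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(tree = default_sim_tree(),
                       n_diploids = c(low1 = 56, low2 = 84, low3 = 49,
                                      high = 249),
                       n_chromosomes = 26, n_snps_per_chrom = 1622,
                       ancestral_range = c(0.05, 0.95),
                       n_founders = 50, switch_rate = 0.05,
                       sweeps = list(), missing_rate = 0,
                       case_populations = "high",
                       bp_spacing = 50000, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  tips <- .tree_tips(tree)
  stopifnot(setequal(names(n_diploids), tips),
            switch_rate >= 0, switch_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            n_founders >= 2)
  if (length(sweeps) && is.infinite(n_founders))
    stop("sweep injection requires a finite founder pool")
  for (sw in sweeps) {
    stopifnot(sw$population %in% tips,
              sw$chrom >= 1, sw$chrom <= n_chromosomes,
              sw$start_snp >= 1, sw$end_snp <= n_snps_per_chrom,
              sw$start_snp <= sw$end_snp, sw$s > 0, sw$s <= 1)
  }
  structure(list(tree = tree, n_diploids = n_diploids[tips],
                 n_chromosomes = as.integer(n_chromosomes),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 ancestral_range = ancestral_range,
                 n_founders = if (is.infinite(n_founders)) Inf
                              else as.integer(n_founders),
                 switch_rate = switch_rate, sweeps = sweeps,
                 missing_rate = missing_rate,
                 case_populations = case_populations,
                 bp_spacing = as.integer(bp_spacing),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_map <- function(cfg) {
  m <- cfg$n_chromosomes * cfg$n_snps_per_chrom
  chrom <- rep(seq_len(cfg$n_chromosomes), each = cfg$n_snps_per_chrom)
  pos_in <- rep(seq_len(cfg$n_snps_per_chrom), cfg$n_chromosomes)
  bp <- pos_in * cfg$bp_spacing
  data.frame(chrom = chrom,
             id = sprintf("snp%d_%d", chrom, pos_in),
             cm = bp / 1e6, bp = bp,
             allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
}

#' Simulate per-population allele frequencies
#'
#' Draws ancestral frequencies uniformly on \code{ancestral_range}, then
#' applies Balding-Nichols drift recursively along the tree: given parent
#' frequency p and branch parameter c, the child frequency is
#' Beta(p(1-c)/c, (1-p)(1-c)/c) (expectation p, variance c p(1-p); c equals
#' the expected F_ST accrued on the branch). Independent across SNPs.
#' Uses \code{set.seed(cfg$seed)}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{ancestral} (length-M vector) and \code{tips}
#'   (populations x SNPs matrix).
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  m <- cfg$n_chromosomes * cfg$n_snps_per_chrom
  anc <- stats::runif(m, cfg$ancestral_range[1], cfg$ancestral_range[2])
  tips <- list()
  drift <- function(p, c) {
    if (c <= 0) return(p)
    out <- p
    inpoly <- p > 0 & p < 1
    shp1 <- p[inpoly] * (1 - c) / c
    shp2 <- (1 - p[inpoly]) * (1 - c) / c
    out[inpoly] <- stats::rbeta(sum(inpoly), shp1, shp2)
    out
  }
  walk <- function(node, p) {
    p_here <- drift(p, node$c)
    if (!is.null(node$pop)) {
      tips[[node$pop]] <<- p_here
    } else {
      for (ch in node$children) walk(ch, p_here)
    }
  }
  walk(cfg$tree, anc)
  pops <- .tree_tips(cfg$tree)
  list(ancestral = anc,
       tips = do.call(rbind, tips[pops]))
}

#' Simulate phased haplotypes with founder-mosaic LD
#'
#' Per population: draw \code{n_founders} founder haplotypes site-wise
#' Bernoulli(tip frequency); each sample haplotype then copies a mosaic of
#' founders, switching to a uniformly redrawn founder at each marker
#' interval with probability \code{switch_rate}. Shared founder segments
#' create LD that decays with distance. Uses \code{set.seed(cfg$seed + 1)}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param freqs result of \code{\link{simulate_frequencies}}.
#' @return object of class \code{haplotype_set}: \code{haps}
#'   (2*sum(n_diploids) x SNPs 0/1 matrix), \code{hap_population},
#'   \code{hap_sample}, \code{samples} (data.frame as in a
#'   \code{genotype_dataset}), \code{snps} (map), \code{truth} (founder
#'   matrices, mosaic paths, tip frequencies, sweep list).
#' @export
simulate_haplotypes <- function(cfg, freqs) {
  set.seed(cfg$seed + 1L)
  map <- .sim_map(cfg)
  L <- nrow(map)
  pops <- .tree_tips(cfg$tree)
  M <- cfg$n_founders
  # founder switching may not cross chromosome boundaries' meaning much;
  # a switch is forced at each chromosome start by redrawing the founder
  chrom_start <- which(!duplicated(map$chrom))
  haps <- NULL
  hap_pop <- character(0)
  founders <- list()
  paths <- list()
  for (pop in pops) {
    p <- freqs$tips[pop, ]
    n_h <- 2L * cfg$n_diploids[[pop]]
    if (is.infinite(M)) {
      # island model: no founder bottleneck, site-wise independent draws
      hp <- matrix(stats::rbinom(n_h * L, 1, rep(p, each = n_h)), n_h, L)
      pth <- matrix(NA_integer_, 0, 0)
    } else {
      fd <- matrix(stats::rbinom(M * L, 1, rep(p, each = M)), M, L)
      founders[[pop]] <- fd
      hp <- matrix(0L, n_h, L)
      pth <- matrix(0L, n_h, L)
      for (i in seq_len(n_h)) {
        switch_at <- c(TRUE, stats::runif(L - 1) < cfg$switch_rate)
        switch_at[chrom_start] <- TRUE
        seg <- cumsum(switch_at)
        fidx <- sample.int(M, max(seg), replace = TRUE)[seg]
        pth[i, ] <- fidx
        hp[i, ] <- fd[cbind(fidx, seq_len(L))]
      }
    }
    haps <- rbind(haps, hp)
    hap_pop <- c(hap_pop, rep(pop, n_h))
    paths[[pop]] <- pth
  }
  n_dip <- sum(cfg$n_diploids)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%03d", p, seq_len(cfg$n_diploids[[p]]))))
  samples <- data.frame(
    id = sample_ids, family = sample_ids,
    population = rep(pops, cfg$n_diploids[pops]),
    group = ifelse(rep(pops, cfg$n_diploids[pops]) %in%
                     cfg$case_populations, "case", "control"),
    stringsAsFactors = FALSE)
  structure(list(haps = haps, hap_population = hap_pop,
                 hap_sample = rep(seq_len(n_dip), each = 2),
                 samples = samples, snps = map,
                 truth = list(founders = founders, paths = paths,
                              tip_freqs = freqs$tips, sweeps = list())),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haps), "haplotypes x", ncol(x$haps),
      "SNPs;", length(unique(x$hap_population)), "populations\n")
  if (length(x$truth$sweeps))
    cat("  sweeps injected:", length(x$truth$sweeps), "\n")
  invisible(x)
}

#' Population allele frequencies of a haplotype set
#'
#' @param hapset a \code{haplotype_set}.
#' @return populations x SNPs matrix.
#' @export
hap_pop_freqs <- function(hapset) {
  pops <- sort(unique(hapset$hap_population))
  out <- matrix(NA_real_, length(pops), ncol(hapset$haps),
                dimnames = list(pops, NULL))
  for (i in seq_along(pops))
    out[i, ] <- colMeans(hapset$haps[hapset$hap_population == pops[i], ,
                                     drop = FALSE])
  out
}

#' Inject a selective sweep
#'
#' Within the sweep's SNP span, the modal founder haplotype of the target
#' population is driven to carrier frequency >= \code{s}: randomly chosen
#' non-carrier haplotypes have their span segment replaced by the founder's
#' segment until the target is met. Haplotypes outside the span and all
#' other populations are untouched. Idempotent when the target frequency is
#' already reached. Uses \code{set.seed(cfg$seed + 2 + sweep index)}.
#'
#' @param hapset a \code{haplotype_set}.
#' @param sweep one sweep spec (see \code{\link{sim_config}}).
#' @param cfg the \code{\link{sim_config}}.
#' @param index index of the sweep (seeds the resampling stream).
#' @return the modified \code{haplotype_set}; the realized sweep (with the
#'   chosen founder and global SNP span) is appended to
#'   \code{truth$sweeps}.
#' @export
inject_sweep <- function(hapset, sweep, cfg, index = 1L) {
  set.seed(cfg$seed + 2L + as.integer(index))
  map <- hapset$snps
  span <- which(map$chrom == sweep$chrom)[sweep$start_snp:sweep$end_snp]
  pop <- sweep$population
  rows <- which(hapset$hap_population == pop)
  n_h <- length(rows)
  k_target <- ceiling(sweep$s * n_h)
  if (k_target > n_h)
    stop("sweep target frequency ", sweep$s, " unreachable")
  paths <- hapset$truth$paths[[pop]][, span, drop = FALSE]
  # modal founder over the span (ties: lowest founder index)
  founder <- as.integer(names(which.max(table(as.vector(paths)))))
  seg <- hapset$truth$founders[[pop]][founder, span]
  carrier <- apply(paths == founder, 1, all)
  n_need <- k_target - sum(carrier)
  if (n_need > 0) {
    conv <- sample(which(!carrier), n_need)
    hapset$haps[rows[conv], span] <- matrix(seg, n_need, length(span),
                                            byrow = TRUE)
    hapset$truth$paths[[pop]][conv, span] <- founder
  }
  hapset$truth$sweeps[[length(hapset$truth$sweeps) + 1L]] <-
    list(population = pop, chrom = sweep$chrom,
         start_snp = sweep$start_snp, end_snp = sweep$end_snp,
         s = sweep$s, founder = founder,
         snp_index = span,
         start_bp = map$bp[span[1]], end_bp = map$bp[span[length(span)]])
  hapset
}

#' Emit a genotype dataset from haplotypes
#'
#' Pairs consecutive haplotypes into diploids, adds i.i.d. missingness, and
#' returns a \code{genotype_dataset} (optionally writing PLINK files).
#' Uses \code{set.seed(cfg$seed + 9)} for the missingness draw.
#'
#' @param hapset a \code{haplotype_set}.
#' @param cfg the \code{\link{sim_config}}.
#' @param missing_rate overrides \code{cfg$missing_rate} when not NULL.
#' @param path_prefix optional PLINK output prefix.
#' @param format PLINK format when writing.
#' @return a \code{genotype_dataset}.
#' @export
emit_dataset <- function(hapset, cfg, missing_rate = NULL,
                         path_prefix = NULL, format = "binary") {
  rate <- missing_rate %||% cfg$missing_rate
  h <- hapset$haps
  odd <- seq(1, nrow(h), by = 2)
  calls <- h[odd, , drop = FALSE] + h[odd + 1, , drop = FALSE]
  if (rate > 0) {
    set.seed(cfg$seed + 9L)
    calls[matrix(stats::runif(length(calls)) < rate,
                 nrow(calls), ncol(calls))] <- NA_integer_
  }
  ds <- genotype_dataset(calls, hapset$samples, hapset$snps)
  if (!is.null(path_prefix)) write_plink(ds, path_prefix, format)
  ds
}

#' One-call simulation
#'
#' Frequencies, haplotypes, sweep injection and dataset emission under one
#' configuration. Fully deterministic given the config (including its
#' seed).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{dataset}, \code{hapset}, \code{freqs},
#'   \code{truth}.
#' @export
simulate_dataset <- function(cfg) {
  freqs <- simulate_frequencies(cfg)
  hs <- simulate_haplotypes(cfg, freqs)
  for (i in seq_along(cfg$sweeps))
    hs <- inject_sweep(hs, cfg$sweeps[[i]], cfg, index = i)
  ds <- emit_dataset(hs, cfg)
  list(dataset = ds, hapset = hs, freqs = freqs, truth = hs$truth)
}

#' Write the simulation truth sidecar
#'
#' Writes the sweep regions as BED (0-based half-open) and the founder
#' mosaic paths as a tab-separated table.
#'
#' @param hapset a \code{haplotype_set}.
#' @param prefix output path prefix (\code{<prefix>_sweeps.bed},
#'   \code{<prefix>_paths.tsv}).
#' @return \code{prefix}, invisibly.
#' @export
write_truth <- function(hapset, prefix) {
  sw <- hapset$truth$sweeps
  bed <- if (length(sw)) {
    do.call(rbind, lapply(sw, function(s) data.frame(
      chrom = s$chrom, start = s$start_bp - 1L, end = s$end_bp,
      name = paste0("sweep_", s$population), score = s$s)))
  } else data.frame(chrom = integer(0), start = integer(0),
                    end = integer(0), name = character(0),
                    score = numeric(0))
  utils::write.table(bed, paste0(prefix, "_sweeps.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- do.call(rbind, lapply(names(hapset$truth$paths), function(p)
    data.frame(population = p,
               hap = seq_len(nrow(hapset$truth$paths[[p]])),
               path = apply(hapset$truth$paths[[p]], 1, paste,
                            collapse = ","))))
  utils::write.table(paths, paste0(prefix, "_paths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
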