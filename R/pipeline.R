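# Pipeline orchestration: the scan stages as named subcommands sharing one
# plain-text (YAML) configuration, with a machine-readable run manifest and
# fixed-seed reproducibility. No timestamps are written, so reruns with an
# identical config and inputs are byte-identical.

.pipeline_defaults <- function() {
  list(
    output_dir = "sweepscan_run",
    seed = 1,
    simulate = list(enabled = TRUE, n_chromosomes = 2,
                    n_snps_per_chrom = 500,
                    n_diploids = list(low1 = 20, low2 = 20, low3 = 20,
                                      high = 20),
                    n_founders = 30, switch_rate = 0.05,
                    missing_rate = 0.01,
                    sweep = list(enabled = TRUE, population = "high",
                                 chrom = 1, start_snp = 200, end_snp = 219,
                                 s = 0.9)),
    genotypes = NULL, popmap = NULL, phenotypes = NULL,
    qc = list(maf_min = 0.05, snp_callrate_min = 0.95,
              sample_missing_max = 0.05, kinship_threshold = 0.354),
    scan = list(window_size_snps = 10, step_snps = 1, top_fraction = 0.001,
                statistic = "wc_theta"),
    hapflk = list(K = 10, n_runs = 20, max_iter = 100, tol = 1e-4,
                  top_fraction = 0.001, law = "normal"),
    annotate = list(genes_bed = NULL, qtl_bed = NULL, flank_bp = 200000)
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills in defaults, and
#' validates it: when simulation is disabled the genotype and population-map
#' paths must exist, and every stochastic stage has an explicit seed
#' (the top-level \code{seed} drives them all).
#'
#' @param config path of a YAML file, or a list.
#' @return validated configuration list (class \code{pipeline_config}).
#' @export
load_pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.pipeline_defaults(), config)
  if (!is.numeric(cfg$seed)) stop("config: seed must be an integer")
  if (!isTRUE(cfg$simulate$enabled)) {
    if (is.null(cfg$genotypes))
      stop("config: genotypes path required when simulate is disabled")
    probe <- paste0(cfg$genotypes, c(".bed", ".ped"))
    if (!any(file.exists(probe)))
      stop("config: no PLINK files at genotype prefix ", cfg$genotypes)
    if (is.null(cfg$popmap) || !file.exists(cfg$popmap))
      stop("config: popmap file required when simulate is disabled")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.pipeline_stages <- c("simulate", "qc", "pca", "fst-scan", "hapflk",
                      "annotate", "report")

.checksum <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(character(0))
  sums <- tools::md5sum(paths)
  stats::setNames(as.vector(sums), basename(names(sums)))
}

#' Run pipeline stages
#'
#' Executes one subcommand or the whole chain
#' (\code{simulate, qc, pca, fst-scan, hapflk, annotate, report}) and
#' writes each stage's outputs plus a machine-readable run manifest
#' (settings, seed, input checksums, outputs) to the output directory.
#' Reruns with identical configuration and inputs are byte-identical.
#'
#' @param config a \code{\link{load_pipeline_config}} input.
#' @param stages \code{"all"} or a subset of the stage names (in pipeline
#'   order).
#' @return the manifest (list of stage records), invisibly; artifacts are
#'   written under \code{config$output_dir}.
#' @export
run_pipeline <- function(config = list(), stages = "all") {
  cfg <- load_pipeline_config(config)
  if (identical(stages, "all")) stages <- .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list()
  for (st in .pipeline_stages) {
    if (!st %in% stages) next
    rec <- tryCatch(.run_stage(st, cfg, state, out),
                    error = function(e)
                      stop("pipeline stage '", st, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    manifest[[length(manifest) + 1L]] <- rec
  }
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

.get_dataset <- function(cfg, state, out, qc = TRUE) {
  key <- if (qc) "ds_qc" else "ds_raw"
  if (!is.null(state[[key]])) return(state[[key]])
  prefix <- file.path(out, if (qc) "genotypes_qc" else "genotypes")
  if (file.exists(paste0(prefix, ".bed"))) {
    ds <- read_plink(prefix, popmap = file.path(out, "popmap.tsv"))
    phen <- file.path(out, "phenotypes.tsv")
    if (file.exists(phen)) ds <- assign_groups(ds, phen)
    state[[key]] <- ds
    return(ds)
  }
  if (!qc) {
    ds <- read_plink(cfg$genotypes, popmap = cfg$popmap)
    if (!is.null(cfg$phenotypes)) ds <- assign_groups(ds, cfg$phenotypes)
    state[[key]] <- ds
    return(ds)
  }
  stop("QC'd genotypes not found; run the qc stage first")
}

.run_stage <- function(st, cfg, state, out) {
  rec <- list(stage = st, seed = cfg$seed)
  if (st == "simulate") {
    if (!isTRUE(cfg$simulate$enabled)) {
      rec$skipped <- TRUE
      return(rec)
    }
    sc <- cfg$simulate
    sweeps <- list()
    if (isTRUE(sc$sweep$enabled))
      sweeps <- list(list(population = sc$sweep$population,
                          chrom = sc$sweep$chrom,
                          start_snp = sc$sweep$start_snp,
                          end_snp = sc$sweep$end_snp, s = sc$sweep$s))
    simc <- sim_config(n_diploids = unlist(sc$n_diploids),
                       n_chromosomes = sc$n_chromosomes,
                       n_snps_per_chrom = sc$n_snps_per_chrom,
                       n_founders = sc$n_founders,
                       switch_rate = sc$switch_rate,
                       missing_rate = sc$missing_rate,
                       sweeps = sweeps, seed = cfg$seed)
    sim <- simulate_dataset(simc)
    prefix <- file.path(out, "genotypes")
    write_plink(sim$dataset, prefix, "binary")
    utils::write.table(
      data.frame(sim$dataset$samples$id, sim$dataset$samples$population),
      file.path(out, "popmap.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    tp <- ifelse(sim$dataset$samples$group == "case", 8L, 2L)
    utils::write.table(
      data.frame(sim$dataset$samples$id, tp),
      file.path(out, "phenotypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    write_truth(sim$hapset, file.path(out, "truth"))
    state$ds_raw <- NULL  # force re-read so downstream sees emitted files
    state$hapset <- sim$hapset
    rec$outputs <- c("genotypes.bed", "genotypes.bim", "genotypes.fam",
                     "popmap.tsv", "phenotypes.tsv", "truth_sweeps.bed")
    rec$checksums <- .checksum(file.path(out, rec$outputs))
  } else if (st == "qc") {
    ds <- .get_dataset(cfg, state, out, qc = FALSE)
    q <- qc_filter(ds, cfg$qc$maf_min, cfg$qc$snp_callrate_min,
                   cfg$qc$sample_missing_max)
    kin <- king_kinship(q$dataset)
    pr <- prune_related(q$dataset, kin, cfg$qc$kinship_threshold)
    state$ds_qc <- pr$dataset
    prefix <- file.path(out, "genotypes_qc")
    write_plink(pr$dataset, prefix, "binary")
    rep_tab <- data.frame(
      metric = c("snps_in", "snps_removed_callrate", "snps_removed_maf",
                 "snps_out", "samples_in", "samples_removed_missing",
                 "samples_removed_relatedness", "samples_out"),
      value = c(q$report$n_snps_input, q$report$n_snps_removed_callrate,
                q$report$n_snps_removed_maf, q$report$n_snps_output,
                q$report$n_samples_input, q$report$n_samples_removed_missing,
                length(pr$removed), nrow(pr$dataset$samples)))
    utils::write.table(rep_tab, file.path(out, "qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rec$outputs <- c("genotypes_qc.bed", "genotypes_qc.bim",
                     "genotypes_qc.fam", "qc_report.tsv")
    rec$checksums <- .checksum(file.path(out, rec$outputs))
  } else if (st == "pca") {
    ds <- .get_dataset(cfg, state, out)
    p <- pca(grm(ds), k = min(10, nrow(ds$samples) - 1))
    write_pca(p, file.path(out, "pca_scores.tsv"),
              populations = ds$samples$population)
    rec$outputs <- c("pca_scores.tsv", "pca_scores.tsv.var")
    rec$checksums <- .checksum(file.path(out, rec$outputs))
  } else if (st == "fst-scan") {
    ds <- .get_dataset(cfg, state, out)
    sc <- scan_config(window_size_snps = cfg$scan$window_size_snps,
                      step_snps = cfg$scan$step_snps,
                      top_fraction = cfg$scan$top_fraction,
                      statistic = cfg$scan$statistic)
    res <- fst_scan(ds, sc)
    state$fst <- res
    utils::write.table(res$per_snp, file.path(out, "fst_per_snp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$windows, file.path(out, "fst_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(res$regions, file.path(out, "fst_regions.bed"))
    rec$outputs <- c("fst_per_snp.tsv", "fst_windows.tsv",
                     "fst_regions.bed")
    rec$checksums <- .checksum(file.path(out, rec$outputs))
    rec$summary <- list(mean_snp_fst = res$mean_snp_fst,
                        n_regions = nrow(res$regions))
  } else if (st == "hapflk") {
    ds <- .get_dataset(cfg, state, out)
    hf <- hapflk_scan(ds, K = cfg$hapflk$K, n_runs = cfg$hapflk$n_runs,
                      max_iter = cfg$hapflk$max_iter, tol = cfg$hapflk$tol,
                      seed = cfg$seed, top_fraction = cfg$hapflk$top_fraction,
                      law = cfg$hapflk$law)
    state$hapflk <- hf
    utils::write.table(hf$per_snp, file.path(out, "hapflk_per_snp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(hf$regions, file.path(out, "hapflk_regions.bed"))
    utils::write.table(hf$kinship$F, file.path(out, "kinship_F.tsv"),
                       sep = "\t", quote = FALSE)
    ape::write.tree(hf$kinship$tree, file.path(out, "kinship_tree.nwk"))
    rec$outputs <- c("hapflk_per_snp.tsv", "hapflk_regions.bed",
                     "kinship_F.tsv", "kinship_tree.nwk")
    rec$checksums <- .checksum(file.path(out, rec$outputs))
  } else if (st == "annotate") {
    if (is.null(state$fst) || is.null(state$hapflk))
      stop("annotate requires the fst-scan and hapflk stages")
    ds <- .get_dataset(cfg, state, out)
    combined <- intersect_method_sets(state$fst$regions,
                                      state$hapflk$regions)
    chrom_len <- tapply(ds$snps$bp, ds$snps$chrom, max) + cfg$annotate$flank_bp
    combined <- flank_regions(combined, cfg$annotate$flank_bp, chrom_len)
    genes <- if (!is.null(cfg$annotate$genes_bed))
      read_bed(cfg$annotate$genes_bed)
    qtls <- if (!is.null(cfg$annotate$qtl_bed))
      read_bed(cfg$annotate$qtl_bed)
    rep_df <- region_report(combined, genes, qtls,
                            file.path(out, "regions_report.tsv"))
    write_bed(combined, file.path(out, "regions_combined.bed"))
    state$combined <- combined
    rec$outputs <- c("regions_report.tsv", "regions_combined.bed")
    rec$checksums <- .checksum(file.path(out, rec$outputs))
    rec$summary <- list(n_regions = nrow(rep_df),
                        n_both = sum(rep_df$method == "both"))
  } else if (st == "report") {
    fst <- state$fst
    hf <- state$hapflk
    summary <- data.frame(
      metric = c("mean_snp_fst", "sd_snp_fst", "mean_window_fst",
                 "n_fst_regions", "n_hapflk_regions", "n_both_regions"),
      value = c(fst$mean_snp_fst, fst$sd_snp_fst, fst$mean_window_fst,
                nrow(fst$regions), nrow(hf$regions),
                if (!is.null(state$combined))
                  sum(state$combined$method == "both") else NA))
    utils::write.table(summary, file.path(out, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rec$outputs <- "summary.tsv"
    rec$checksums <- .checksum(file.path(out, rec$outputs))
  }
  rec
}
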