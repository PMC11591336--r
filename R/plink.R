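# PLINK 1.9 text (.ped/.map) and binary (.bed/.bim/.fam) input/output.
# Binary .bed is SNP-major with magic bytes 6C 1B 01; two-bit codes
# 00 = hom allele1, 01 = missing, 10 = het, 11 = hom allele2.
# The text dialect carries no allele-role designation, so allele1/allele2
# are inferred from allele counts (minor first, ties lexicographic);
# binary preserves them exactly.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> dosages of the 4 packed genotypes (NA = missing)
.bed_decode_table <- local({
  tab <- matrix(NA_integer_, 256, 4)
  code2dose <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      tab[b + 1L, s + 1L] <- code2dose[[as.character(code)]]
    }
  }
  tab
})

.dose2code <- function(d) {
  # dosage (0,1,2,NA) -> two-bit code
  out <- integer(length(d))
  out[is.na(d)] <- 1L
  out[!is.na(d) & d == 1L] <- 2L
  out[!is.na(d) & d == 2L] <- 3L
  out
}

.read_popmap <- function(popmap) {
  if (is.null(popmap)) return(NULL)
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap)) {
    tab <- utils::read.table(popmap, header = FALSE, stringsAsFactors = FALSE)
    popmap <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  } else if (is.data.frame(popmap)) {
    popmap <- stats::setNames(as.character(popmap[[2]]), as.character(popmap[[1]]))
  }
  popmap
}

.parse_chrom <- function(x) {
  # numeric codes pass through; X/Y/XY/MT and unknowns become non-autosomal
  suppressWarnings(ch <- as.integer(x))
  ch[is.na(ch)] <- -1L
  ch
}

#' Read PLINK-format genotypes
#'
#' Reads a \code{.ped}/\code{.map} pair (\code{format = "text"}) or a
#' \code{.bed}/\code{.bim}/\code{.fam} triple (\code{format = "binary"}) into
#' a \code{\link{genotype_dataset}}. Dosages count copies of \code{allele2}.
#' Non-autosomal records (chromosome codes outside \code{autosomes}) are
#' dropped with a reported count; sheep autosomes 1-26 are the default.
#'
#' @param path_prefix path without extension.
#' @param format \code{"auto"} (detect from files present), \code{"text"} or
#'   \code{"binary"}.
#' @param popmap optional sample-to-population mapping: a named character
#'   vector, a two-column data.frame, or the path of a two-column
#'   whitespace-separated file (sample-id, population).
#' @param autosomes integer vector of autosomal chromosome codes.
#' @return a \code{genotype_dataset}; the number of dropped non-autosomal
#'   SNPs is attached as attribute \code{"n_dropped_nonautosomal"}.
#' @export
read_plink <- function(path_prefix, format = c("auto", "text", "binary"),
                       popmap = NULL, autosomes = 1:26) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(path_prefix, ".bed"))) "binary" else "text"
  }
  popmap <- .read_popmap(popmap)
  raw <- if (format == "binary") .read_plink_binary(path_prefix)
         else .read_plink_text(path_prefix)
  chrom <- .parse_chrom(raw$snps$chrom)
  keep <- chrom %in% autosomes
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_plink: dropped ", n_drop, " non-autosomal SNP(s)")
  raw$snps$chrom <- chrom
  ds <- genotype_dataset(raw$calls[, keep, drop = FALSE],
                         raw$samples, raw$snps[keep, , drop = FALSE])
  if (!is.null(popmap)) {
    absent <- setdiff(names(popmap), ds$samples$id)
    if (length(absent))
      warning("popmap sample(s) absent from genotype files: ",
              paste(absent, collapse = ", "))
    hit <- match(ds$samples$id, names(popmap))
    ds$samples$population <- ifelse(is.na(hit), "unassigned", popmap[hit])
  }
  validate_genotype_dataset(ds)
  attr(ds, "n_dropped_nonautosomal") <- n_drop
  ds
}

.read_map_like <- function(path, n_cols) {
  if (length(readLines(path, n = 1L)) == 0L) {
    tab <- as.data.frame(matrix(character(0), 0, n_cols),
                         stringsAsFactors = FALSE)
    return(tab)
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != n_cols)
    stop("expected ", n_cols, " columns in ", path, ", found ", ncol(tab))
  tab
}

.read_plink_text <- function(path_prefix) {
  map_path <- paste0(path_prefix, ".map")
  ped_path <- paste0(path_prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop("missing .ped/.map files at prefix ", path_prefix)
  map <- .read_map_like(map_path, 4L)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  samples <- data.frame(id = character(n), family = character(n),
                        population = "unassigned", group = "unassigned",
                        stringsAsFactors = FALSE)
  amat <- bmat <- matrix("0", n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * m)
      stop("ped line ", i, ": expected ", 6L + 2L * m, " fields (",
           m, " SNPs in .map), found ", length(tok))
    samples$family[i] <- tok[1]
    samples$id[i] <- tok[2]
    amat[i, ] <- tok[seq(7L, by = 2L, length.out = m)]
    bmat[i, ] <- tok[seq(8L, by = 2L, length.out = m)]
  }
  # allele roles inferred per SNP from allele counts: allele1 = minor,
  # allele2 = major; ties broken lexicographically (allele1 sorts first)
  calls <- matrix(NA_integer_, n, m)
  allele1 <- rep("0", m)
  allele2 <- rep("0", m)
  for (j in seq_len(m)) {
    al <- c(amat[, j], bmat[, j])
    counts <- table(al[al != "0"])
    if (length(counts) > 2)
      stop("SNP ", map[[2]][j], " has more than two alleles in ", ped_path)
    if (length(counts) == 2) {
      nm <- names(counts)[order(counts, names(counts))]
      allele1[j] <- nm[1]
      allele2[j] <- nm[2]
    } else if (length(counts) == 1) {
      allele2[j] <- names(counts)  # monomorphic: single allele is allele2
    }
    miss <- amat[, j] == "0" | bmat[, j] == "0"
    calls[!miss, j] <- (amat[!miss, j] == allele2[j]) +
      (bmat[!miss, j] == allele2[j])
  }
  snps <- data.frame(chrom = map[[1]], id = map[[2]],
                     cm = as.numeric(map[[3]]), bp = as.integer(map[[4]]),
                     allele1 = allele1, allele2 = allele2,
                     stringsAsFactors = FALSE)
  list(calls = calls, samples = samples, snps = snps)
}

.read_plink_binary <- function(path_prefix) {
  bed_path <- paste0(path_prefix, ".bed")
  bim_path <- paste0(path_prefix, ".bim")
  fam_path <- paste0(path_prefix, ".fam")
  if (!all(file.exists(c(bed_path, bim_path, fam_path))))
    stop("missing .bed/.bim/.fam files at prefix ", path_prefix)
  bim <- .read_map_like(bim_path, 6L)
  fam <- .read_map_like(fam_path, 6L)
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed_path, "raw", n = 3L + bytes_per_snp * m + 8L)
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("not a SNP-major PLINK .bed file (bad magic bytes): ", bed_path)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop(".bed payload size (", length(body), ") inconsistent with ",
         n, " samples x ", m, " SNPs")
  calls <- matrix(NA_integer_, n, m)
  if (m > 0 && n > 0) {
    bmat <- matrix(as.integer(body), bytes_per_snp, m)
    # expand each byte column into 4 dosage rows via the lookup table
    big <- matrix(t(.bed_decode_table[bmat + 1L, , drop = FALSE]),
                  nrow = 4L * bytes_per_snp, ncol = m)
    calls <- big[seq_len(n), , drop = FALSE]
  }
  samples <- data.frame(id = fam[[2]], family = fam[[1]],
                        population = "unassigned", group = "unassigned",
                        stringsAsFactors = FALSE)
  snps <- data.frame(chrom = bim[[1]], id = bim[[2]],
                     cm = as.numeric(bim[[3]]), bp = as.integer(bim[[4]]),
                     allele1 = bim[[5]], allele2 = bim[[6]],
                     stringsAsFactors = FALSE)
  list(calls = calls, samples = samples, snps = snps)
}

#' Write PLINK-format genotypes
#'
#' Writes text (\code{.ped}/\code{.map}, tab-separated, missing genotype
#' \code{"0 0"}) or binary (\code{.bed}/\code{.bim}/\code{.fam}) files that
#' \code{\link{read_plink}} reads back with bit-identical calls.
#'
#' @param ds a \code{genotype_dataset}.
#' @param path_prefix output path without extension.
#' @param format \code{"text"} or \code{"binary"}.
#' @return \code{path_prefix}, invisibly.
#' @export
write_plink <- function(ds, path_prefix, format = c("text", "binary")) {
  format <- match.arg(format)
  validate_genotype_dataset(ds)
  dir.create(dirname(path_prefix), recursive = TRUE, showWarnings = FALSE)
  if (format == "text") .write_plink_text(ds, path_prefix)
  else .write_plink_binary(ds, path_prefix)
  invisible(path_prefix)
}

.write_plink_text <- function(ds, path_prefix) {
  map <- ds$snps
  utils::write.table(
    data.frame(map$chrom, map$id, map$cm, map$bp),
    paste0(path_prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(ds$samples)
  m <- nrow(ds$snps)
  con <- file(paste0(path_prefix, ".ped"), "w")
  on.exit(close(con))
  a1 <- ds$snps$allele1
  a2 <- ds$snps$allele2
  a1[a1 == "0" & a2 != "0"] <- a2[a1 == "0" & a2 != "0"]  # monomorphic SNPs
  for (i in seq_len(n)) {
    d <- ds$calls[i, ]
    first <- ifelse(is.na(d), "0", ifelse(d == 0L, a1, ifelse(d == 1L, a1, a2)))
    second <- ifelse(is.na(d), "0", ifelse(d == 0L, a1, a2))
    geno <- character(2L * m)
    if (m > 0) {
      geno[seq(1L, by = 2L, length.out = m)] <- first
      geno[seq(2L, by = 2L, length.out = m)] <- second
    }
    writeLines(paste(c(ds$samples$family[i], ds$samples$id[i],
                       "0", "0", "0", "-9", geno), collapse = "\t"), con)
  }
}

.write_plink_binary <- function(ds, path_prefix) {
  bim <- ds$snps
  utils::write.table(
    data.frame(bim$chrom, bim$id, bim$cm, bim$bp, bim$allele1, bim$allele2),
    paste0(path_prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- ds$samples
  utils::write.table(
    data.frame(fam$family, fam$id, "0", "0", "0", "-9"),
    paste0(path_prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(ds$samples)
  m <- nrow(ds$snps)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  if (m > 0) {
    codes <- matrix(0L, 4L * bytes_per_snp, m)
    codes[seq_len(n), ] <- matrix(.dose2code(ds$calls), n, m, byrow = FALSE)
    idx <- rep(seq_len(bytes_per_snp), each = 4L)
    w <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
    bytes <- rowsum(codes * w, idx)  # bytes_per_snp x m
    writeBin(as.raw(bytes), con)
  }
}
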