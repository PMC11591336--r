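# Sweep-region post-processing: flanking, cross-method intersection, and
# overlap with gene/QTL annotation intervals. Internal coordinates are
# 1-based inclusive; BED files are 0-based half-open and converted at the
# boundary.

.regions_granges <- function(regions, use_flanked = FALSE) {
  start <- if (use_flanked && "flank_start" %in% names(regions))
    regions$flank_start else regions$start_bp
  end <- if (use_flanked && "flank_end" %in% names(regions))
    regions$flank_end else regions$end_bp
  GenomicRanges::GRanges(seqnames = as.character(regions$chrom),
                         ranges = IRanges::IRanges(start = start, end = end))
}

#' Add flanks to sweep regions
#'
#' Extends each region by \code{flank_bp} on both sides, clamped to
#' [1, chromosome length].
#'
#' @param regions data.frame with \code{chrom}, \code{start_bp},
#'   \code{end_bp} (1-based inclusive).
#' @param flank_bp flank size (default 200000, i.e. 200 kb).
#' @param chrom_lengths named vector (chromosome -> length in bp) covering
#'   every region chromosome.
#' @return \code{regions} with added \code{flank_start}, \code{flank_end}.
#' @export
flank_regions <- function(regions, flank_bp = 200000, chrom_lengths) {
  if (!nrow(regions)) {
    regions$flank_start <- integer(0); regions$flank_end <- integer(0)
    return(regions)
  }
  lens <- chrom_lengths[as.character(regions$chrom)]
  if (any(is.na(lens)))
    stop("chrom_lengths missing chromosome(s): ",
         paste(unique(regions$chrom[is.na(lens)]), collapse = ", "))
  if (any(regions$end_bp > lens))
    stop("region end beyond chromosome length on chromosome(s): ",
         paste(unique(regions$chrom[regions$end_bp > lens]), collapse = ", "))
  regions$flank_start <- pmax(1, regions$start_bp - flank_bp)
  regions$flank_end <- pmin(lens, regions$end_bp + flank_bp)
  regions
}

#' Label regions by detecting method
#'
#' Regions from two scans that overlap by at least 1 bp on the same
#' chromosome are merged (interval union, maximum statistic) and labeled
#' \code{"both"}; all others keep their own method label.
#'
#' @param fst_regions,hapflk_regions region data.frames with \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{stat}, \code{method}.
#' @return combined region data.frame sorted by (chromosome, start).
#' @export
intersect_method_sets <- function(fst_regions, hapflk_regions) {
  if (!nrow(fst_regions) && !nrow(hapflk_regions))
    return(fst_regions)
  fst_regions$method <- if (nrow(fst_regions)) "FST" else character(0)
  hapflk_regions$method <- if (nrow(hapflk_regions)) "hapFLK" else character(0)
  common <- intersect(names(fst_regions), names(hapflk_regions))
  all_r <- rbind(fst_regions[common], hapflk_regions[common])
  gr <- .regions_granges(all_r)
  is_fst <- seq_len(nrow(all_r)) <= nrow(fst_regions)
  hits <- GenomicRanges::findOverlaps(gr[is_fst], gr[!is_fst])
  fi <- which(is_fst)[S4Vectors::queryHits(hits)]
  hi <- which(!is_fst)[S4Vectors::subjectHits(hits)]
  merged <- list()
  used <- logical(nrow(all_r))
  if (length(fi)) {
    # connected cross-method components via union of the paired intervals
    comp <- GenomicRanges::reduce(c(gr[unique(fi)], gr[unique(hi)]))
    inv <- GenomicRanges::findOverlaps(gr, comp)
    for (ci in seq_along(comp)) {
      members <- S4Vectors::queryHits(inv)[S4Vectors::subjectHits(inv) == ci]
      members <- members[used[members] == FALSE & members %in% c(fi, hi)]
      if (!length(members)) next
      used[members] <- TRUE
      sub <- all_r[members, , drop = FALSE]
      merged[[length(merged) + 1L]] <- data.frame(
        chrom = sub$chrom[1], start_bp = min(sub$start_bp),
        end_bp = max(sub$end_bp), stat = max(sub$stat),
        method = "both")
    }
  }
  keep <- all_r[!used, c("chrom", "start_bp", "end_bp", "stat", "method"),
                drop = FALSE]
  out <- rbind(keep, do.call(rbind, merged))
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap regions with named annotation intervals
#'
#' Reports every annotation name whose interval overlaps the (flanked, when
#' available) region by at least 1 bp. Output preserves region order; names
#' within a region are sorted by annotation start.
#'
#' @param regions region data.frame (optionally flanked via
#'   \code{\link{flank_regions}}).
#' @param annotation data.frame with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive; use \code{\link{read_bed}} for BED input),
#'   \code{name}.
#' @param use_flanked use the flanked coordinates when present
#'   (default TRUE).
#' @return list (one character vector of names per region).
#' @export
overlap_annotations <- function(regions, annotation, use_flanked = TRUE) {
  if (!nrow(regions)) return(list())
  if (nrow(annotation)) {
    unmatched <- setdiff(unique(as.character(annotation$chrom)),
                         unique(as.character(regions$chrom)))
    if (length(unmatched) == length(unique(annotation$chrom)))
      stop("no annotation chromosome matches any region chromosome; ",
           "unmatched: ", paste(unmatched, collapse = ", "))
  }
  rg <- .regions_granges(regions, use_flanked = use_flanked)
  ann <- annotation[order(annotation$chrom, annotation$start), , drop = FALSE]
  ag <- GenomicRanges::GRanges(as.character(ann$chrom),
                               IRanges::IRanges(ann$start, ann$end))
  hits <- GenomicRanges::findOverlaps(rg, ag)
  out <- rep(list(character(0)), nrow(regions))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (i in unique(q)) out[[i]] <- as.character(ann$name[s[q == i]])
  out
}

#' Read a BED file
#'
#' BED is 0-based half-open; the returned intervals are 1-based inclusive.
#'
#' @param path BED3+ file (chrom, start, end, and optionally name, score).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           sep = "\t", comment.char = "#")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]) + 1L,
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    paste0("feature", seq_len(nrow(tab)))
  out$score <- if (ncol(tab) >= 5) as.numeric(tab[[5]]) else NA_real_
  out
}

#' Write regions as BED
#'
#' Converts the 1-based inclusive internal coordinates to 0-based
#' half-open.
#'
#' @param regions region data.frame (\code{chrom}, \code{start_bp},
#'   \code{end_bp}; optional \code{stat}, \code{method}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- if ("method" %in% names(regions)) regions$method
          else rep("region", nrow(regions))
  score <- if ("stat" %in% names(regions)) regions$stat
           else rep(0, nrow(regions))
  tab <- data.frame(regions$chrom, regions$start_bp - 1L, regions$end_bp,
                    name, score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Human-readable region report
#'
#' Tab-separated table with one row per region: chromosome, span,
#' midpoint location, peak statistic, gene and QTL name lists, method.
#'
#' @param regions flanked region data.frame.
#' @param genes,qtls optional annotation data.frames (see
#'   \code{\link{overlap_annotations}}).
#' @param path optional output path.
#' @return the report data.frame (written to \code{path} when given).
#' @export
region_report <- function(regions, genes = NULL, qtls = NULL, path = NULL) {
  rep_df <- data.frame(
    chrom = regions$chrom,
    span = sprintf("%d-%d", regions$start_bp, regions$end_bp),
    location = round((regions$start_bp + regions$end_bp) / 2),
    stat = regions$stat,
    genes = "-", qtl = "-",
    method = if ("method" %in% names(regions)) regions$method else "FST",
    stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(regions)) {
    g <- overlap_annotations(regions, genes)
    rep_df$genes <- vapply(g, function(x)
      if (length(x)) paste(x, collapse = ",") else "-", "")
  }
  if (!is.null(qtls) && nrow(regions)) {
    q <- overlap_annotations(regions, qtls)
    rep_df$qtl <- vapply(q, function(x)
      if (length(x)) paste(x, collapse = ",") else "-", "")
  }
  if (!is.null(path))
    utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep_df
}
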