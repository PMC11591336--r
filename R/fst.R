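# Per-SNP Weir-Cockerham theta and Wright-style F_ST, creeping-window
# smoothing, empirical-percentile outlier windows, and region merging.

.resolve_grouping <- function(ds, grouping) {
  if (is.null(grouping)) {
    g <- ds$samples$group
    g[g == "unassigned"] <- NA
  } else if (length(grouping) == 1L && is.character(grouping) &&
             grouping == "population") {
    g <- ds$samples$population
  } else {
    stopifnot(length(grouping) == nrow(ds$samples))
    g <- as.character(grouping)
  }
  factor(g)
}

.group_site_stats <- function(ds, grouping) {
  # per-group, per-SNP non-missing sample count, allele2 frequency and
  # observed heterozygote proportion
  g <- .resolve_grouping(ds, grouping)
  lev <- levels(droplevels(g))
  r <- length(lev)
  if (r < 2) stop("grouping must yield at least 2 non-empty groups")
  m <- nrow(ds$snps)
  n <- p <- h <- matrix(0, r, m, dimnames = list(lev, NULL))
  for (i in seq_len(r)) {
    rows <- which(g == lev[i])
    x <- ds$calls[rows, , drop = FALSE]
    obs <- !is.na(x)
    ni <- colSums(obs)
    n[i, ] <- ni
    sum_x <- colSums(x, na.rm = TRUE)
    p[i, ] <- ifelse(ni > 0, sum_x / (2 * ni), NA_real_)
    h[i, ] <- ifelse(ni > 0, colSums(x == 1L, na.rm = TRUE) / ni, NA_real_)
  }
  list(n = n, p = p, h = h, r = r, groups = lev)
}

#' Per-SNP Weir-Cockerham theta
#'
#' The unbiased fixation-index estimator of Weir & Cockerham (1984) for
#' \code{r} groups, returning the three variance components per SNP:
#' \code{a} (between groups), \code{b} (between individuals within groups),
#' \code{c} (within individuals), and \eqn{\theta = a/(a+b+c)}. A SNP is
#' undefined when \eqn{a+b+c = 0} (monomorphic across the pooled groups) or
#' when any group has no non-missing call.
#'
#' @param ds a \code{genotype_dataset}.
#' @param grouping \code{NULL} (use the case/control labels of
#'   \code{ds$samples$group}; unassigned samples are excluded),
#'   \code{"population"} (one group per population), or a vector of group
#'   labels per sample (\code{NA} = excluded).
#' @return data.frame with one row per SNP: \code{snp}, \code{chrom},
#'   \code{bp}, \code{id}, \code{a}, \code{b}, \code{c}, \code{theta},
#'   \code{defined}.
#' @export
wc_theta_per_snp <- function(ds, grouping = NULL) {
  st <- .group_site_stats(ds, grouping)
  n <- st$n; p <- st$p; h <- st$h; r <- st$r
  m <- ncol(n)
  any_empty <- colSums(n == 0) > 0
  nbar <- colSums(n) / r
  sum_n2 <- colSums(n^2)
  nc <- (r * nbar - sum_n2 / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (inner - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  defined <- !any_empty & is.finite(tot) & tot != 0
  theta <- ifelse(defined, a / tot, NA_real_)
  a[any_empty] <- b[any_empty] <- cc[any_empty] <- NA_real_
  n_empty <- sum(any_empty)
  if (n_empty > 0)
    message("wc_theta_per_snp: ", n_empty,
            " SNP(s) undefined (a group with zero non-missing calls)")
  data.frame(snp = seq_len(m), chrom = ds$snps$chrom, bp = ds$snps$bp,
             id = ds$snps$id, a = a, b = b, c = cc, theta = theta,
             defined = defined, stringsAsFactors = FALSE)
}

#' Per-SNP Wright-style F_ST
#'
#' Nei's \eqn{F_{ST} = (H_T - H_S)/H_T} with expected heterozygosities
#' weighted by per-group non-missing sample size; undefined when
#' \eqn{H_T = 0}.
#'
#' @inheritParams wc_theta_per_snp
#' @return data.frame with per-SNP \code{hs}, \code{ht}, \code{theta}
#'   (the F_ST value, kept under the common column name for window reuse)
#'   and \code{defined}.
#' @export
wright_fst_per_snp <- function(ds, grouping = NULL) {
  st <- .group_site_stats(ds, grouping)
  n <- st$n; p <- st$p
  m <- ncol(n)
  any_empty <- colSums(n == 0) > 0
  ntot <- colSums(n)
  pbar <- colSums(n * p) / ntot
  ht <- 2 * pbar * (1 - pbar)
  hs <- colSums(n * 2 * p * (1 - p)) / ntot
  defined <- !any_empty & is.finite(ht) & ht > 0
  fst <- ifelse(defined, (ht - hs) / ht, NA_real_)
  data.frame(snp = seq_len(m), chrom = ds$snps$chrom, bp = ds$snps$bp,
             id = ds$snps$id, hs = hs, ht = ht, theta = fst,
             defined = defined, stringsAsFactors = FALSE)
}

#' Scan configuration
#'
#' Bundles the windowing and thresholding settings of the F_ST scan.
#'
#' @param window_size_snps SNPs per window (default 10).
#' @param step_snps step between window starts in SNPs (default 1: the
#'   "creeping" window).
#' @param top_fraction fraction of windows called significant
#'   (default 0.001, i.e. the top 0.1\%).
#' @param statistic \code{"wc_theta"} or \code{"wright"}.
#' @param window_stat \code{"mean"} (arithmetic mean of per-SNP values) or
#'   \code{"ratio_of_sums"} (multi-locus \eqn{\sum a / \sum(a+b+c)};
#'   Weir-Cockerham only).
#' @param clamp_negative clamp negative per-SNP values to 0 before averaging
#'   (default \code{FALSE}).
#' @param min_defined_frac windows with a smaller fraction of defined SNPs
#'   are dropped (default 0.5).
#' @return a list of class \code{scan_config}.
#' @export
scan_config <- function(window_size_snps = 10, step_snps = 1,
                        top_fraction = 0.001,
                        statistic = c("wc_theta", "wright"),
                        window_stat = c("mean", "ratio_of_sums"),
                        clamp_negative = FALSE, min_defined_frac = 0.5) {
  stopifnot(window_size_snps >= 1, step_snps >= 1,
            top_fraction > 0, top_fraction < 1)
  structure(list(window_size_snps = as.integer(window_size_snps),
                 step_snps = as.integer(step_snps),
                 top_fraction = top_fraction,
                 statistic = match.arg(statistic),
                 window_stat = match.arg(window_stat),
                 clamp_negative = isTRUE(clamp_negative),
                 min_defined_frac = min_defined_frac),
            class = "scan_config")
}

#' Creeping-window smoothing of per-SNP statistics
#'
#' Slides a window of \code{window_size_snps} adjacent SNPs along each
#' chromosome, advancing \code{step_snps} SNPs at a time (one SNP by
#' default), and averages the defined per-SNP values in each window. A
#' chromosome with L SNPs yields \code{max(L - window + 1, 0)} windows at
#' step 1. Windows in which fewer than \code{min_defined_frac} of the SNPs
#' are defined are dropped (a message reports how many).
#'
#' @param per_snp data.frame from \code{\link{wc_theta_per_snp}} or
#'   \code{\link{wright_fst_per_snp}}, in map order.
#' @param cfg a \code{\link{scan_config}}.
#' @return data.frame with one row per retained window: \code{chrom},
#'   \code{first_snp}/\code{last_snp} (global SNP row indices),
#'   \code{start_bp}/\code{end_bp}, \code{stat} (window value),
#'   \code{n_defined}.
#' @export
creeping_windows <- function(per_snp, cfg = scan_config()) {
  w <- cfg$window_size_snps
  step <- cfg$step_snps
  vals <- per_snp$theta
  if (cfg$clamp_negative) vals <- pmax(vals, 0)
  def <- per_snp$defined & !is.na(vals)
  use_ratio <- cfg$window_stat == "ratio_of_sums"
  if (use_ratio && !all(c("a", "b", "c") %in% names(per_snp)))
    stop("ratio_of_sums window statistic requires Weir-Cockerham components")
  out <- list()
  for (ch in unique(per_snp$chrom)) {
    idx <- which(per_snp$chrom == ch)
    L <- length(idx)
    if (L < w) next
    starts <- seq(1L, L - w + 1L, by = step)
    v <- vals[idx]; d <- def[idx]
    v0 <- ifelse(d, v, 0)
    cs_v <- c(0, cumsum(v0))
    cs_d <- c(0, cumsum(as.numeric(d)))
    nd <- cs_d[starts + w] - cs_d[starts]
    if (use_ratio) {
      asum <- ifelse(d, per_snp$a[idx], 0)
      tsum <- ifelse(d, per_snp$a[idx] + per_snp$b[idx] + per_snp$c[idx], 0)
      cs_a <- c(0, cumsum(asum)); cs_t <- c(0, cumsum(tsum))
      stat <- (cs_a[starts + w] - cs_a[starts]) /
        (cs_t[starts + w] - cs_t[starts])
    } else {
      stat <- (cs_v[starts + w] - cs_v[starts]) / nd
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, first_snp = idx[starts], last_snp = idx[starts + w - 1L],
      start_bp = per_snp$bp[idx[starts]], end_bp = per_snp$bp[idx[starts + w - 1L]],
      stat = stat, n_defined = nd)
  }
  if (!length(out))
    return(data.frame(chrom = integer(0), first_snp = integer(0),
                      last_snp = integer(0), start_bp = integer(0),
                      end_bp = integer(0), stat = numeric(0),
                      n_defined = numeric(0)))
  win <- do.call(rbind, out)
  low <- win$n_defined < cfg$min_defined_frac * w
  if (any(low))
    message("creeping_windows: dropped ", sum(low),
            " window(s) with < ", cfg$min_defined_frac * 100, "% defined SNPs")
  win <- win[!low, , drop = FALSE]
  rownames(win) <- NULL
  win
}

#' Fixed-size base-pair windows
#'
#' Companion to \code{\link{creeping_windows}} using physical window
#' boundaries (e.g. 600 kb) instead of SNP counts. Windows with no defined
#' SNP are dropped.
#'
#' @param per_snp per-SNP statistic table (see \code{creeping_windows}).
#' @param size_bp window width in bp (default 600000).
#' @param step_bp step between window starts in bp (default \code{size_bp}).
#' @return data.frame as in \code{creeping_windows}, with bp-defined
#'   boundaries.
#' @export
bp_windows <- function(per_snp, size_bp = 600000, step_bp = size_bp) {
  out <- list()
  for (ch in unique(per_snp$chrom)) {
    idx <- which(per_snp$chrom == ch)
    bp <- per_snp$bp[idx]
    starts <- seq(1, max(bp), by = step_bp)
    for (s in starts) {
      inw <- idx[bp >= s & bp < s + size_bp]
      d <- inw[per_snp$defined[inw]]
      if (!length(d)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, first_snp = min(inw), last_snp = max(inw),
        start_bp = s, end_bp = s + size_bp - 1,
        stat = mean(per_snp$theta[d]), n_defined = length(d))
    }
  }
  if (!length(out)) return(creeping_windows(per_snp[0, , drop = FALSE]))
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  win
}

#' Empirical top-fraction threshold
#'
#' Calls significant the windows whose statistic reaches the empirical
#' \code{1 - top_fraction} quantile: the \code{ceiling(top_fraction * n)}-th
#' largest value is the threshold and ties with it are included.
#'
#' @param windows data.frame from \code{\link{creeping_windows}}.
#' @param top_fraction fraction of windows to call (0, 1).
#' @return list with \code{threshold} (numeric), \code{significant}
#'   (subset of \code{windows}) and \code{n_selected}.
#' @export
threshold_top <- function(windows, top_fraction = 0.001) {
  stopifnot(nrow(windows) >= 1, top_fraction > 0, top_fraction < 1)
  k <- ceiling(top_fraction * nrow(windows))
  thr <- sort(windows$stat, decreasing = TRUE)[k]
  sig <- windows[windows$stat >= thr, , drop = FALSE]
  sig <- sig[order(sig$chrom, sig$start_bp), , drop = FALSE]
  rownames(sig) <- NULL
  list(threshold = thr, significant = sig, n_selected = nrow(sig))
}

#' Merge significant windows into sweep regions
#'
#' Windows on the same chromosome that share at least one SNP or directly
#' abut in SNP index are merged into one contiguous region. The region
#' statistic is the maximum window statistic.
#'
#' @param significant data.frame of significant windows (see
#'   \code{\link{threshold_top}}).
#' @param method label to attach (\code{"FST"}, \code{"hapFLK"}, ...).
#' @return data.frame of regions sorted by (chromosome, start): \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{first_snp}, \code{last_snp},
#'   \code{stat} (peak), \code{n_windows}, \code{method}.
#' @export
windows_to_regions <- function(significant, method = "FST") {
  if (!nrow(significant))
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), first_snp = integer(0),
                      last_snp = integer(0), stat = numeric(0),
                      n_windows = integer(0), method = character(0)))
  s <- significant[order(significant$chrom, significant$first_snp), ,
                   drop = FALSE]
  out <- list()
  cur <- s[1, ]
  for (i in seq_len(nrow(s))[-1]) {
    row <- s[i, ]
    if (row$chrom == cur$chrom && row$first_snp <= cur$last_snp + 1L) {
      cur$last_snp <- max(cur$last_snp, row$last_snp)
      cur$end_bp <- max(cur$end_bp, row$end_bp)
      cur$start_bp <- min(cur$start_bp, row$start_bp)
      cur$stat <- max(cur$stat, row$stat)
      cur$n_defined <- cur$n_defined + row$n_defined
      cur$n_win <- (cur$n_win %||% 1L) + 1L
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  reg <- do.call(rbind, lapply(out, function(r) data.frame(
    chrom = r$chrom, start_bp = r$start_bp, end_bp = r$end_bp,
    first_snp = r$first_snp, last_snp = r$last_snp, stat = r$stat,
    n_windows = r$n_win %||% 1L)))
  reg <- reg[order(reg$chrom, reg$start_bp), , drop = FALSE]
  reg$method <- method
  rownames(reg) <- NULL
  reg
}

#' Run the full F_ST scan
#'
#' Convenience wrapper: per-SNP statistic, creeping windows, top-fraction
#' threshold and region merging in one call.
#'
#' @param ds a \code{genotype_dataset} with case/control groups assigned
#'   (or an explicit \code{grouping}).
#' @param cfg a \code{\link{scan_config}}.
#' @param grouping see \code{\link{wc_theta_per_snp}}.
#' @return list with \code{per_snp}, \code{windows}, \code{threshold},
#'   \code{significant}, \code{regions}, and genome-wide means
#'   \code{mean_snp_fst} / \code{mean_window_fst}.
#' @export
fst_scan <- function(ds, cfg = scan_config(), grouping = NULL) {
  per_snp <- if (cfg$statistic == "wc_theta") wc_theta_per_snp(ds, grouping)
             else wright_fst_per_snp(ds, grouping)
  windows <- creeping_windows(per_snp, cfg)
  top <- threshold_top(windows, cfg$top_fraction)
  regions <- windows_to_regions(top$significant, method = "FST")
  list(per_snp = per_snp, windows = windows, threshold = top$threshold,
       significant = top$significant, regions = regions,
       mean_snp_fst = mean(per_snp$theta[per_snp$defined]),
       sd_snp_fst = stats::sd(per_snp$theta[per_snp$defined]),
       mean_window_fst = mean(windows$stat),
       sd_window_fst = stats::sd(windows$stat))
}
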