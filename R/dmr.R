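#' Call differentially methylated regions between two methylomes
#'
#' Candidate units are the sliding windows of \code{\link{scan_windows}},
#' restricted to CpGs covered in both samples. For every window with at
#' least \code{min_cpgs_per_window} shared CpGs, the methylation difference
#' is the difference of unweighted per-CpG means (B minus A) and the p-value
#' comes from a two-sided exact test on the pooled methylated/unmethylated
#' read counts across the window's shared CpGs (a 2x2 sample-by-state
#' table). Benjamini-Hochberg q-values are computed over all tested windows
#' genome-wide; a window is differentially methylated when |diff| exceeds
#' \code{dmr_min_diff} and q is below \code{dmr_max_q}. Overlapping or
#' book-ended windows of the same direction are merged; merged regions
#' recompute their statistics over all shared CpGs in the merged span and
#' inherit the minimum p/q of their constituents.
#'
#' Pooling counts within a window is conservative when true levels vary
#' between CpGs of the same window, and gives a transparent exact-test
#' oracle; this caller makes no attempt to reproduce any specific published
#' DMR package beyond the three criteria above.
#'
#' @param meth_a,meth_b Strand-merged \code{\link{methylome}} objects on the
#'   same genome.
#' @param params An \code{\link{analysis_params}}.
#' @return Data.frame of regions: \code{chrom, start, end, n_cpg, mean_a,
#'   mean_b, mean_level, kind = "DMR", diff, p, q, direction} where
#'   direction is \code{"hyper"} (B above A) or \code{"hypo"}.
#' @export
call_dmrs <- function(meth_a, meth_b, params = analysis_params()) {
  st <- dmr_window_stats(meth_a, meth_b, params)
  win <- st$windows
  shared <- st$shared

  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_a = numeric(), mean_b = numeric(),
                      mean_level = numeric(), kind = character(),
                      diff = numeric(), p = numeric(), q = numeric(),
                      direction = character())
  if (!nrow(win)) return(empty)
  sig <- win[abs(win$diff) > params$dmr_min_diff & win$q < params$dmr_max_q, ,
             drop = FALSE]
  if (!nrow(sig)) return(empty)
  sig$direction <- ifelse(sig$diff > 0, "hyper", "hypo")

  out <- list()
  for (dir in unique(sig$direction)) {
    s <- sig[sig$direction == dir, , drop = FALSE]
    merged <- GenomicRanges::reduce(regions_granges(s))
    hits <- GenomicRanges::findOverlaps(
      calls_granges(data.frame(chrom = shared$chrom, pos = shared$pos)),
      merged)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    nm <- length(merged)
    n_cpg <- tabulate(sh, nbins = nm)
    mean_a <- tapply2(shared$la[qh], sh, nm) / pmax(n_cpg, 1L)
    mean_b <- tapply2(shared$lb[qh], sh, nm) / pmax(n_cpg, 1L)
    # constituent-window min p/q per merged region
    wh <- GenomicRanges::findOverlaps(regions_granges(s), merged)
    pmin_ <- rep(NA_real_, nm); qmin_ <- rep(NA_real_, nm)
    for (j in seq_len(nm)) {
      wj <- S4Vectors::queryHits(wh)[S4Vectors::subjectHits(wh) == j]
      pmin_[j] <- min(s$p[wj]); qmin_[j] <- min(s$q[wj])
    }
    out[[dir]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(merged)),
      start = GenomicRanges::start(merged) - 1L,
      end = GenomicRanges::end(merged),
      n_cpg = n_cpg, mean_a = mean_a, mean_b = mean_b,
      mean_level = mean_b, kind = "DMR",
      diff = mean_b - mean_a, p = pmin_, q = qmin_, direction = dir)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window differential methylation statistics
#'
#' The candidate-window table behind \code{\link{call_dmrs}}: every sliding
#' window with at least \code{min_cpgs_per_window} CpGs covered in both
#' samples, with unweighted per-CpG means for each sample, their difference,
#' pooled read counts, the two-sided exact p-value and the
#' Benjamini-Hochberg q-value over all tested windows. Exposed so that
#' genome-wide calibration (the fraction of rejected windows under a null
#' contrast) can be inspected directly.
#'
#' @inheritParams call_dmrs
#' @return List with \code{windows} (the tested-window data.frame) and
#'   \code{shared} (the per-CpG table of positions covered in both samples).
#' @export
dmr_window_stats <- function(meth_a, meth_b, params = analysis_params()) {
  stopifnot(inherits(meth_a, "methylome"), inherits(meth_b, "methylome"))
  if (!meth_a$merged || !meth_b$merged) {
    stop("methylomes have stranded CpG calls; run merge_cpg_strands() first")
  }
  a <- meth_calls(meth_a, context = "CG")
  b <- meth_calls(meth_b, context = "CG")
  i <- match(paste(a$chrom, a$pos), paste(b$chrom, b$pos))
  keep <- !is.na(i)
  if (!any(keep)) stop("no CpG positions covered in both methylomes")
  shared <- data.frame(
    chrom = a$chrom[keep], pos = a$pos[keep],
    la = a$level[keep], lb = b$level[i[keep]],
    ma = a$n_meth[keep], ua = a$n_total[keep] - a$n_meth[keep],
    mb = b$n_meth[i[keep]], ub = b$n_total[i[keep]] - b$n_meth[i[keep]])

  contigs <- meth_contigs(meth_a)
  size <- params$window_size
  step <- params$window_step

  win <- list()
  for (contig in names(contigs)) {
    len <- as.integer(contigs[[contig]])
    cc <- shared[shared$chrom == contig, , drop = FALSE]
    if (!nrow(cc)) next
    starts <- seq.int(0L, max(len - 1L, 0L), by = step)
    starts <- starts[starts < len]
    n_win <- length(starts)
    acc <- matrix(0, n_win, 7L)  # n, la, lb, ma, ua, mb, ub
    for (k in 0:(ceiling(size / step) - 1L)) {
      wi <- cc$pos %/% step - k
      ok <- wi >= 0L & wi < n_win & cc$pos < (wi * step + size)
      if (!any(ok)) next
      idx <- wi[ok] + 1L
      acc[, 1L] <- acc[, 1L] + tabulate(idx, nbins = n_win)
      for (j in 2:7) {
        acc[, j] <- acc[, j] +
          tapply2(cc[[c("la", "lb", "ma", "ua", "mb", "ub")[j - 1L]]][ok],
                  idx, n_win)
      }
    }
    el <- acc[, 1L] >= params$min_cpgs_per_window
    if (!any(el)) next
    win[[contig]] <- data.frame(
      chrom = contig, start = starts[el],
      end = pmin(starts + size, len)[el],
      n_cpg = acc[el, 1L],
      mean_a = acc[el, 2L] / acc[el, 1L],
      mean_b = acc[el, 3L] / acc[el, 1L],
      ma = acc[el, 4L], ua = acc[el, 5L],
      mb = acc[el, 6L], ub = acc[el, 7L])
  }
  if (!length(win)) {
    win <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_a = numeric(), mean_b = numeric(),
                      ma = numeric(), ua = numeric(), mb = numeric(),
                      ub = numeric(), diff = numeric(), p = numeric(),
                      q = numeric())
    return(list(windows = win, shared = shared))
  }
  win <- do.call(rbind, win)
  rownames(win) <- NULL
  win$diff <- win$mean_b - win$mean_a
  win$p <- fisher_exact_2x2(win$ma, win$ua, win$mb, win$ub)
  win$q <- stats::p.adjust(win$p, method = "BH")
  list(windows = win, shared = shared)
}

#' Two-sided exact p-values for 2x2 count tables
#'
#' Conditional (hypergeometric) exact test identical to the two-sided
#' Fisher test: the p-value sums the probabilities of all tables, with the
#' observed margins, whose likelihood does not exceed the observed table's.
#' Vectorized over tables so thousands of windows can be tested cheaply.
#'
#' @param ma,ua Methylated/unmethylated read counts in sample A.
#' @param mb,ub Methylated/unmethylated read counts in sample B.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_2x2 <- function(ma, ua, mb, ub) {
  n <- length(ma)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- ma[i] + ua[i]          # reads in sample A
    nn <- mb[i] + ub[i]         # reads in sample B
    k <- ma[i] + mb[i]          # methylated reads overall
    if (m == 0 || nn == 0 || k == 0 || k == m + nn) { p[i] <- 1; next }
    support <- max(0, k - nn):min(k, m)
    d <- stats::dhyper(support, m, nn, k)
    p[i] <- min(1, sum(d[d <= stats::dhyper(ma[i], m, nn, k) * (1 + 1e-7)]))
  }
  p
}

#' Fraction of DMRs overlapping transposable elements
#'
#' A DMR colocalizes with a TE when it overlaps any TE interval by at least
#' one base; fractions are reported separately for hypo- and
#' hypermethylated DMRs, \code{NA} when a direction has no DMRs.
#'
#' @param dmrs DMR data.frame from \code{\link{call_dmrs}}.
#' @param te A \code{\link{feature_set}} of TE copies.
#' @return Data.frame: \code{direction, n_dmrs, n_overlapping, fraction}.
#' @export
dmr_te_fraction <- function(dmrs, te) {
  dirs <- c("hypo", "hyper")
  out <- data.frame(direction = dirs, n_dmrs = 0L, n_overlapping = 0L,
                    fraction = NA_real_)
  for (j in seq_along(dirs)) {
    d <- dmrs[dmrs$direction == dirs[j], , drop = FALSE]
    out$n_dmrs[j] <- nrow(d)
    if (nrow(d) && nrow(te)) {
      ov <- IRanges::overlapsAny(regions_granges(d), regions_granges(te))
      out$n_overlapping[j] <- sum(ov)
    }
    if (nrow(d)) out$fraction[j] <- out$n_overlapping[j] / nrow(d)
  }
  out
}
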