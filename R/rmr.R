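#' Scan a methylome with sliding windows
#'
#' Tiles every contig with sliding windows (default 500 bp, 250 bp offset)
#' starting at coordinate 0, the final partial window at the contig end being
#' evaluated as-is. Each window reports the number of covered CpGs inside it
#' and the unweighted mean of their per-CpG levels (one CpG, one vote), or
#' the read-pooled level if \code{pooled = TRUE}. Windows with fewer than
#' \code{min_cpgs_per_window} covered CpGs are flagged ineligible.
#'
#' @param x A strand-merged \code{\link{methylome}}.
#' @param params An \code{\link{analysis_params}}.
#' @param pooled If \code{TRUE}, window levels pool read counts instead of
#'   averaging per-CpG levels.
#' @return Data.frame with columns \code{chrom, start, end, n_cpg,
#'   mean_level, eligible} (0-based half-open coordinates).
#' @export
scan_windows <- function(x, params = analysis_params(), pooled = FALSE) {
  stopifnot(inherits(x, "methylome"))
  if (!x$merged) {
    stop("methylome has stranded CpG calls; run merge_cpg_strands() first")
  }
  calls <- meth_calls(x, context = "CG")
  contigs <- meth_contigs(x)
  size <- params$window_size
  step <- params$window_step

  out <- lapply(names(contigs), function(contig) {
    len <- as.integer(contigs[[contig]])
    starts <- seq.int(0L, max(len - 1L, 0L), by = step)
    starts <- starts[starts < len]
    n_win <- length(starts)
    cc <- calls[calls$chrom == contig, , drop = FALSE]
    n_cpg <- integer(n_win)
    lv_sum <- numeric(n_win)
    nm_sum <- numeric(n_win)
    nt_sum <- numeric(n_win)
    if (nrow(cc)) {
      # each CpG falls in at most ceiling(size/step) windows
      for (k in 0:(ceiling(size / step) - 1L)) {
        wi <- cc$pos %/% step - k
        ok <- wi >= 0L & wi < n_win & cc$pos < (wi * step + size)
        if (!any(ok)) next
        idx <- wi[ok] + 1L
        n_cpg <- n_cpg + tabulate(idx, nbins = n_win)
        lv_sum <- lv_sum + unname(tapply2(cc$level[ok], idx, n_win))
        nm_sum <- nm_sum + unname(tapply2(cc$n_meth[ok], idx, n_win))
        nt_sum <- nt_sum + unname(tapply2(cc$n_total[ok], idx, n_win))
      }
    }
    mean_level <- if (pooled) ifelse(nt_sum > 0, nm_sum / nt_sum, NA_real_)
                  else ifelse(n_cpg > 0, lv_sum / n_cpg, NA_real_)
    data.frame(chrom = contig, start = starts,
               end = pmin(starts + size, len),
               n_cpg = n_cpg, mean_level = mean_level,
               eligible = n_cpg >= params$min_cpgs_per_window)
  })
  do.call(rbind, out)
}

# sum of v grouped by integer index 1..n
tapply2 <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Call residually methylated regions (RMRs)
#'
#' A window qualifies as residually methylated when it is eligible (at least
#' \code{min_cpgs_per_window} covered CpGs) and its mean level is strictly
#' greater than \code{rmr_min_level} ("more than 30%"). Qualifying windows
#' that overlap or are book-ended are merged into one region spanning the
#' union of their coordinates, and the region's CpG count and mean level are
#' recomputed over all covered CpGs in the merged span.
#'
#' @param windows Output of \code{\link{scan_windows}}.
#' @param x The \code{\link{methylome}} the windows were computed from (used
#'   to recompute region-level statistics over merged spans).
#' @param params An \code{\link{analysis_params}}.
#' @param trim_to_cpg If \code{TRUE}, merged region coordinates are trimmed
#'   to the outermost covered CpG dyad instead of the union window span.
#' @return Data.frame of regions: \code{chrom, start, end, n_cpg,
#'   mean_level, kind = "RMR"}, sorted by position.
#' @export
call_rmrs <- function(windows, x, params = analysis_params(),
                      trim_to_cpg = FALSE) {
  stopifnot(inherits(x, "methylome"))
  qual <- windows[windows$eligible &
                    !is.na(windows$mean_level) &
                    windows$mean_level > params$rmr_min_level, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_level = numeric(), kind = character())
  if (!nrow(qual)) return(empty)

  merged <- GenomicRanges::reduce(regions_granges(qual))  # book-ended merge
  calls <- meth_calls(x, context = "CG")
  hits <- GenomicRanges::findOverlaps(calls_granges(calls), merged)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_cpg <- tabulate(sh, nbins = length(merged))
  lv <- tapply2(calls$level[qh], sh, length(merged))

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_cpg = n_cpg,
    mean_level = ifelse(n_cpg > 0, lv / n_cpg, NA_real_),
    kind = "RMR")
  if (trim_to_cpg && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      p <- calls$pos[qh[sh == i]]
      if (length(p)) {
        out$start[i] <- min(p)
        out$end[i] <- max(p) + 2L
      }
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CpGs common to two region sets
#'
#' Positions of covered CpGs lying inside at least one region of set A and
#' at least one region of set B (e.g. CpGs common to RMRs called in female
#' and male E13.5 PGCs).
#'
#' @param rmrs_a,rmrs_b Region data.frames (\code{chrom, start, end}).
#' @param x The \code{\link{methylome}} supplying CpG positions.
#' @return Data.frame \code{chrom, pos} of common CpGs; the count is
#'   \code{nrow()} of the result.
#' @export
intersect_rmr_cpgs <- function(rmrs_a, rmrs_b, x) {
  calls <- meth_calls(x, context = "CG")
  if (!nrow(calls) || !nrow(rmrs_a) || !nrow(rmrs_b)) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  gr <- calls_granges(calls)
  in_a <- IRanges::overlapsAny(gr, regions_granges(rmrs_a))
  in_b <- IRanges::overlapsAny(gr, regions_granges(rmrs_b))
  out <- calls[in_a & in_b, c("chrom", "pos")]
  rownames(out) <- NULL
  out
}

#' Two-way overlap counts between region sets
#'
#' A region is "shared" when it overlaps any region of the other set by at
#' least one base; because overlap need not be one-to-one, shared counts are
#' reported from each side separately (as in a two-set Venn diagram of RMRs).
#'
#' @param rmrs_a,rmrs_b Region data.frames.
#' @return Named list: \code{a_only}, \code{shared_a}, \code{shared_b},
#'   \code{b_only}.
#' @export
venn_overlap <- function(rmrs_a, rmrs_b) {
  if (!nrow(rmrs_a) || !nrow(rmrs_b)) {
    return(list(a_only = nrow(rmrs_a), shared_a = 0L, shared_b = 0L,
                b_only = nrow(rmrs_b)))
  }
  ga <- regions_granges(rmrs_a)
  gb <- regions_granges(rmrs_b)
  sa <- sum(IRanges::overlapsAny(ga, gb))
  sb <- sum(IRanges::overlapsAny(gb, ga))
  list(a_only = length(ga) - sa, shared_a = sa,
       shared_b = sb, b_only = length(gb) - sb)
}
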