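#' Shuffle regions within their contigs
#'
#' Generates a length-matched null region set: each region is replaced by a
#' uniformly placed interval of identical length on its own contig
#' (rejection sampling keeps placements in bounds). Keeping placements on
#' the source contig preserves contig composition, which matters on small
#' multi-contig genomes. Deterministic under a fixed seed.
#'
#' @param regions Region data.frame (\code{chrom, start, end}).
#' @param contigs Named vector of contig lengths.
#' @param seed Integer seed.
#' @return Data.frame with the same columns and identical length multiset.
#' @export
shuffle_regions <- function(regions, contigs, seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  lens <- regions$end - regions$start
  clen <- contigs[regions$chrom]
  if (any(is.na(clen))) stop("region on undeclared contig")
  if (any(lens > clen)) stop("region longer than its contig")
  new_start <- floor(stats::runif(nrow(regions)) * (clen - lens + 1))
  out <- regions
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_start + lens)
  out
}

#' Mean signal profile around region centers
#'
#' For every center, the window \code{[center - flank, center + flank)} is
#' split into \code{n_bins} equal bins and the per-base mean of a bedGraph
#' signal (absent intervals count as 0) is computed per bin; the profile is
#' the across-centers mean of each bin. Centers whose window would be
#' truncated by a contig edge are dropped and counted in the
#' \code{"n_edge_dropped"} attribute.
#'
#' @param signal Data.frame \code{chrom, start, end, value} (0-based
#'   half-open bedGraph intervals).
#' @param centers Data.frame with \code{chrom} and either \code{pos} or
#'   \code{start}/\code{end} (midpoints are used).
#' @param contigs Named vector of contig lengths.
#' @param flank Half-window width in bp.
#' @param n_bins Number of bins across the 2 x flank window.
#' @return Numeric vector of length \code{n_bins} (mean signal per bin),
#'   with bin start offsets as names.
#' @export
metaprofile <- function(signal, centers, contigs, flank = 5000L,
                        n_bins = 100L) {
  if (!"pos" %in% names(centers)) {
    centers$pos <- (centers$start + centers$end) %/% 2L
  }
  clen <- contigs[centers$chrom]
  ok <- !is.na(clen) & centers$pos - flank >= 0 & centers$pos + flank <= clen
  n_dropped <- sum(!ok)
  centers <- centers[ok, , drop = FALSE]
  if (!nrow(centers)) stop("no usable centers after edge filtering")
  bin_w <- 2 * flank / n_bins

  n_c <- nrow(centers)
  bin_start <- as.vector(outer(seq_len(n_bins) - 1L, centers$pos - flank,
                               function(b, p) p + b * bin_w))
  gr_bins <- GenomicRanges::GRanges(
    rep(centers$chrom, each = n_bins),
    IRanges::IRanges(start = round(bin_start) + 1L, width = round(bin_w)))
  gr_sig <- regions_granges(signal)
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_sig)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_bins)[qh], IRanges::ranges(gr_sig)[sh]))
  contrib <- ov * signal$value[sh]
  sums <- numeric(n_c * n_bins)
  if (length(qh)) {
    agg <- rowsum(contrib, qh)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  per_bin_mean <- sums / round(bin_w)
  prof <- rowMeans(matrix(per_bin_mean, nrow = n_bins))
  names(prof) <- as.character(seq(-flank, flank - bin_w, by = bin_w))
  attr(prof, "n_centers") <- n_c
  attr(prof, "n_edge_dropped") <- n_dropped
  prof
}

#' Transposable-element family composition of a region set
#'
#' Per TE family, the fraction of regions overlapping at least one copy by
#' at least one base; a region overlapping several families is counted once
#' per family, so the per-family fractions may sum above 1. A
#' mutually-exclusive view assigns each region to the family with the
#' largest overlap in bases (\code{"none"} when a region overlaps no TE).
#'
#' @param regions Region data.frame.
#' @param te A \code{\link{feature_set}} of TE copies.
#' @return List of two data.frames: \code{per_family} (\code{family,
#'   n_regions, fraction}) and \code{exclusive} (majority-overlap
#'   assignment, fractions summing to 1).
#' @export
te_composition <- function(regions, te) {
  n <- nrow(regions)
  fams <- unique(te$family)
  per <- data.frame(family = c(fams, "none"), n_regions = 0L,
                    fraction = NA_real_)
  assign <- rep("none", n)
  if (n && nrow(te)) {
    gr_r <- regions_granges(regions)
    gr_t <- regions_granges(te)
    hits <- GenomicRanges::findOverlaps(gr_r, gr_t)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_r)[qh], IRanges::ranges(gr_t)[sh]))
    fam_hit <- te$family[sh]
    for (j in seq_along(fams)) {
      per$n_regions[j] <- length(unique(qh[fam_hit == fams[j]]))
    }
    # majority-overlap assignment
    if (length(qh)) {
      key <- paste(qh, fam_hit)
      bases <- rowsum(ov, key)
      kq <- as.integer(sub(" .*", "", rownames(bases)))
      kf <- sub("^[0-9]+ ", "", rownames(bases))
      o <- order(kq, -bases[, 1L], kf)
      first <- !duplicated(kq[o])
      assign[kq[o][first]] <- kf[o][first]
    }
  }
  per$n_regions[per$family == "none"] <- sum(assign == "none")
  if (n) per$fraction <- per$n_regions / n
  excl <- as.data.frame(table(factor(assign, levels = per$family)),
                        stringsAsFactors = FALSE)
  names(excl) <- c("family", "n_regions")
  excl$fraction <- if (n) excl$n_regions / n else NA_real_
  list(per_family = per, exclusive = excl)
}

#' Upper-tail hypergeometric overlap probability
#'
#' Significance of the overlap between two gene (or region) sets drawn from
#' a common universe: the probability of observing at least
#' \code{n_overlap} shared elements when \code{n_set_a} and \code{n_set_b}
#' elements are drawn without replacement from \code{n_universe}.
#'
#' @param n_universe Universe size.
#' @param n_set_a,n_set_b Sizes of the two sets.
#' @param n_overlap Observed overlap.
#' @return P(X >= n_overlap) for X hypergeometric.
#' @export
overlap_hypergeometric <- function(n_universe, n_set_a, n_set_b, n_overlap) {
  if (n_overlap < 0 || n_set_a > n_universe || n_set_b > n_universe ||
      n_overlap > min(n_set_a, n_set_b)) {
    stop("inconsistent overlap counts")
  }
  stats::phyper(n_overlap - 1, n_set_a, n_universe - n_set_a, n_set_b,
                lower.tail = FALSE)
}

#' Empirical enrichment p-value from shuffled nulls
#'
#' Compares an observed statistic with its values over shuffled-region
#' nulls using the add-one estimator (r + 1) / (n + 1), which can never
#' return zero.
#'
#' @param observed Observed statistic.
#' @param null_values Statistic over shuffled region sets.
#' @return Empirical upper-tail p-value.
#' @export
empirical_pvalue <- function(observed, null_values) {
  (sum(null_values >= observed) + 1) / (length(null_values) + 1)
}
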