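#' Table of non-CpG (CH) methylation calls
#'
#' Extracts all stranded CH calls (CA, CC, CT) from a methylome and
#' summarizes the mean level and site count per context class; CpG calls
#' are excluded. The per-context summary is attached as the
#' \code{"summary"} attribute.
#'
#' @param x A \code{\link{methylome}}.
#' @return Data.frame of CH calls (\code{chrom, pos, strand, context,
#'   n_meth, n_total, level}) with attribute \code{summary}: a data.frame
#'   \code{context, n_sites, mean_level}.
#' @export
ch_site_table <- function(x) {
  stopifnot(inherits(x, "methylome"))
  ch <- meth_calls(x, context = c("CA", "CC", "CT"))
  rownames(ch) <- NULL
  if (!nrow(ch)) {
    warning("methylome contains no CH calls")
    attr(ch, "summary") <- data.frame(context = character(),
                                      n_sites = integer(),
                                      mean_level = numeric())
    return(ch)
  }
  s <- data.frame(
    context = sort(unique(ch$context)),
    n_sites = as.integer(table(ch$context)[sort(unique(ch$context))]),
    mean_level = as.numeric(tapply(ch$level, ch$context,
                                   mean)[sort(unique(ch$context))]))
  rownames(s) <- NULL
  attr(ch, "summary") <- s
  ch
}

#' Sequence-context frequency matrix of methylated CH sites
#'
#' For every CH site with observed methylation strictly above
#' \code{min_level} (default 2%), extracts the flanking genomic sequence
#' (\code{flank} bases each side of the cytosine), reverse-complementing
#' minus-strand contexts so that offset +1 is always the base 3' of the
#' methylated C. Returns the per-offset base frequency matrix, the standard
#' input for sequence-logo rendering. Sites within \code{flank} of a contig
#' edge are dropped; their count is reported in the \code{"n_edge_dropped"}
#' attribute.
#'
#' @param x A \code{\link{methylome}} containing stranded CH calls.
#' @param genome Named character vector of contig sequences (or a
#'   \code{sim_genome}).
#' @param min_level Level a site must strictly exceed to be included.
#' @param flank Number of flanking bases on each side.
#' @return Matrix with rows A, C, G, T and columns offsets
#'   \code{-flank .. +flank}; every column sums to 1, and offset 0 is 100% C.
#' @export
context_frequency_matrix <- function(x, genome, min_level = 0.02,
                                     flank = 5L) {
  stopifnot(inherits(x, "methylome"))
  if (inherits(genome, "sim_genome")) genome <- genome$sequence
  ch <- meth_calls(x, context = c("CA", "CC", "CT"))
  ch <- ch[ch$level > min_level, , drop = FALSE]
  if (!nrow(ch)) stop("no CH sites above the methylation floor")

  lens <- vapply(genome, nchar, numeric(1L))
  if (anyNA(lens[ch$chrom])) {
    stop("no sequence available for contig ",
         ch$chrom[which(is.na(lens[ch$chrom]))[1L]])
  }
  edge <- ch$pos < flank | ch$pos + flank >= lens[ch$chrom]
  n_edge <- sum(edge)
  ch <- ch[!edge, , drop = FALSE]
  if (!nrow(ch)) stop("all qualifying CH sites fall within 'flank' of a contig edge")

  ctx <- substr(rep(genome[ch$chrom], 1L),
                ch$pos + 1L - flank, ch$pos + 1L + flank)
  minus <- ch$strand == "-"
  if (any(minus)) ctx[minus] <- revcomp(ctx[minus])

  bases <- strsplit(ctx, "")
  w <- 2L * flank + 1L
  mat <- matrix(0, nrow = 4L, ncol = w,
                dimnames = list(c("A", "C", "G", "T"),
                                as.character(seq(-flank, flank))))
  for (j in seq_len(w)) {
    col <- vapply(bases, `[[`, character(1L), j)
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    mat[, j] <- as.numeric(tab) / length(col)
  }
  attr(mat, "n_sites") <- nrow(ch)
  attr(mat, "n_edge_dropped") <- n_edge
  mat
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Coupling between CpA and CpG methylation across windows
#'
#' De novo CpA methylation in remethylating male germ cells tracks local
#' CpG methylation; this statistic quantifies the coupling as the Spearman
#' rank correlation between per-window mean CpA and mean CpG levels, over
#' windows containing at least one call of each kind.
#'
#' @param x A \code{\link{methylome}} with both CG and CA calls.
#' @param window_size Tile width in bp.
#' @return List: \code{rho} (Spearman correlation, \code{NA} when either
#'   series is constant) and \code{n} (number of windows used).
#' @export
cpa_cpg_coupling <- function(x, window_size = 500L) {
  cg <- window_means(x, size = window_size, context = "CG")
  ca <- window_means(x, size = window_size, context = "CA")
  j <- compare_samples(cg, ca, keys = c("chrom", "start"))
  if (nrow(j) < 3L) stop("fewer than 3 windows contain both CpG and CpA calls")
  if (stats::sd(j$level_a) == 0 || stats::sd(j$level_b) == 0) {
    warning("constant window series; correlation undefined")
    return(list(rho = NA_real_, n = nrow(j)))
  }
  list(rho = stats::cor(j$level_a, j$level_b, method = "spearman"),
       n = nrow(j))
}
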