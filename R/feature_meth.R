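#' Aggregate CpG methylation over annotation features
#'
#' Computes, per family or per individual copy, the unweighted mean of all
#' covered CpG levels overlapping the group's intervals, the number of
#' covered CpGs, and how many of the group's copies are covered by at least
#' one call. A CpG overlapping two nested or overlapping features is counted
#' in both groups -- RepeatMasker-style annotations overlap by design, so no
#' ownership resolution is attempted. Groups with no covered CpG are
#' reported with \code{n_cpg = 0} and an undefined mean.
#'
#' @param x A \code{\link{methylome}}.
#' @param features A \code{\link{feature_set}}.
#' @param group_by \code{"family"} or \code{"copy"} (the name column).
#' @param pooled If \code{TRUE}, levels pool read counts instead of
#'   averaging per-CpG levels.
#' @return Data.frame: \code{group, mean_level, n_cpg, n_copies_covered,
#'   n_copies_total}.
#' @export
aggregate_by_feature <- function(x, features,
                                 group_by = c("family", "copy"),
                                 pooled = FALSE) {
  stopifnot(inherits(x, "methylome"))
  group_by <- match.arg(group_by)
  grp <- if (group_by == "family") features$family else features$name
  groups <- unique(grp)
  calls <- meth_calls(x, context = "CG")

  covered <- rep(FALSE, nrow(features))
  stat <- data.frame(group = groups, mean_level = NA_real_, n_cpg = 0L,
                     n_copies_covered = 0L,
                     n_copies_total = as.integer(table(grp)[groups]))
  if (nrow(calls) && nrow(features)) {
    hits <- GenomicRanges::findOverlaps(calls_granges(calls),
                                        regions_granges(features))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    covered[unique(sh)] <- TRUE
    g <- grp[sh]
    if (length(qh)) {
      n <- tapply(qh, g, length)
      lv <- if (pooled) {
        tapply(calls$n_meth[qh], g, sum) / tapply(calls$n_total[qh], g, sum)
      } else {
        tapply(calls$level[qh], g, mean)
      }
      i <- match(names(n), stat$group)
      stat$n_cpg[i] <- as.integer(n)
      stat$mean_level[i] <- as.numeric(lv)
    }
  }
  cov_by_grp <- tapply(covered, grp, sum)
  stat$n_copies_covered <- as.integer(cov_by_grp[stat$group])
  rownames(stat) <- NULL
  stat
}

#' Mean methylation in non-overlapping genomic tiles
#'
#' Splits every contig into adjacent tiles of \code{size} bp and reports the
#' unweighted mean CpG level per tile; tiles without covered CpGs are
#' omitted. This is the summary used for between-sample correlation plots of
#' methylation levels.
#'
#' @param x A strand-merged \code{\link{methylome}}.
#' @param size Tile width in bp.
#' @param context Calls to aggregate (default CpG).
#' @return Data.frame: \code{chrom, start, end, n_cpg, mean_level}.
#' @export
window_means <- function(x, size = 500L, context = "CG") {
  stopifnot(inherits(x, "methylome"))
  calls <- meth_calls(x, context = context)
  if (!nrow(calls)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_level = numeric()))
  }
  tile <- calls$pos %/% size
  key <- paste(calls$chrom, tile)
  lv <- tapply(calls$level, key, mean)
  n <- tapply(calls$level, key, length)
  first <- !duplicated(key)
  out <- data.frame(chrom = calls$chrom[first],
                    start = as.integer(tile[first] * size),
                    n_cpg = as.integer(n[key[first]]),
                    mean_level = as.numeric(lv[key[first]]))
  out$end <- out$start + as.integer(size)
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "n_cpg", "mean_level")]
  rownames(out) <- NULL
  out
}

#' Join two window/feature methylation tables and compute deltas
#'
#' Inner join on the shared keys with \code{delta = b - a}; optionally keeps
#' only rows where sample A exceeds a floor (e.g. tiles above 5% methylation
#' in wild type, so that erasure in the mutant is measured where there was
#' something to erase).
#'
#' @param table_a,table_b Data.frames sharing key columns and a
#'   \code{mean_level} column (e.g. from \code{\link{window_means}} or
#'   \code{\link{aggregate_by_feature}}).
#' @param min_wt_level Optional floor applied to sample A's level.
#' @param keys Key columns for the join; defaults to the common columns
#'   among \code{chrom, start, end, group}.
#' @return Joined data.frame with \code{level_a, level_b, delta}.
#' @export
compare_samples <- function(table_a, table_b, min_wt_level = NULL,
                            keys = intersect(c("chrom", "start", "end",
                                               "group"),
                                             intersect(names(table_a),
                                                       names(table_b)))) {
  stopifnot(length(keys) >= 1L,
            "mean_level" %in% names(table_a),
            "mean_level" %in% names(table_b))
  ka <- do.call(paste, table_a[keys])
  kb <- do.call(paste, table_b[keys])
  i <- match(ka, kb)
  keep <- !is.na(i)
  out <- table_a[keep, keys, drop = FALSE]
  out$level_a <- table_a$mean_level[keep]
  out$level_b <- table_b$mean_level[i[keep]]
  out$delta <- out$level_b - out$level_a
  if (!nrow(out)) warning("no shared keys between the two tables")
  if (!is.null(min_wt_level)) {
    out <- out[!is.na(out$level_a) & out$level_a > min_wt_level, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Luminometric methylation assay (LUMA) estimator
#'
#' Global CpG methylation from a HpaII/MspI digestion assay: HpaII cuts CCGG
#' only when unmethylated, MspI cuts regardless, and EcoRI provides internal
#' normalization of DNA input. The estimate is
#' \deqn{1 - \frac{HpaII / EcoRI_{HpaII}}{MspI / EcoRI_{MspI}}}
#' clipped to [0, 1] to guard against assay noise producing normalized
#' ratios above 1.
#'
#' @param hpaII_peak HpaII peak height (>= 0).
#' @param mspI_peak,ecoRI_hpaII,ecoRI_mspI Strictly positive peak heights.
#' @return Methylation fraction in [0, 1].
#' @export
luma_estimate <- function(hpaII_peak, mspI_peak, ecoRI_hpaII, ecoRI_mspI) {
  if (any(c(mspI_peak, ecoRI_hpaII, ecoRI_mspI) <= 0)) {
    stop("MspI and EcoRI peak heights must be strictly positive")
  }
  if (hpaII_peak < 0) stop("HpaII peak height must be non-negative")
  ratio <- (hpaII_peak / ecoRI_hpaII) / (mspI_peak / ecoRI_mspI)
  min(max(1 - ratio, 0), 1)
}
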