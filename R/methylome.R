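VALID_CONTEXTS <- c("CG", "CA", "CC", "CT")

#' Per-sample collection of cytosine methylation calls
#'
#' A \code{methylome} holds one sample's per-cytosine counts together with the
#' sample descriptors the pipeline needs downstream (developmental stage, sex,
#' genotype) and the depth filter that was applied on construction.
#'
#' Calls use 0-based plus-strand reference coordinates: \code{pos} is the
#' position of the cytosine itself, so the C of a CpG dyad on the minus strand
#' sits one base 3' of its plus-strand partner (\code{pos + 1}). Levels are
#' always recomputed from counts, never trusted from input files.
#'
#' @param calls A data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{context} (one of CG, CA, CC,
#'   CT), \code{n_meth}, \code{n_total}.
#' @param sample_id Sample identifier.
#' @param stage Developmental stage label (ordering is supplied externally by
#'   a sample sheet, never parsed from the label).
#' @param sex One of \code{"male"}, \code{"female"}, \code{"mixed"}.
#' @param genotype One of \code{"WT"}, \code{"Uhrf2KO"}, \code{"Dnmt1cKO"},
#'   \code{"other"}.
#' @param min_depth Minimum read depth; calls with \code{n_total} below this
#'   are dropped on construction.
#' @param contigs Optional named vector of contig lengths; required by window
#'   operations when it cannot be inferred.
#' @param merged Logical; \code{TRUE} once CpG dyads have been strand-merged
#'   (see \code{\link{merge_cpg_strands}}).
#'
#' @return An object of class \code{"methylome"}.
#' @export
methylome <- function(calls,
                      sample_id = "sample",
                      stage = NA_character_,
                      sex = c("mixed", "male", "female"),
                      genotype = c("WT", "Uhrf2KO", "Dnmt1cKO", "other"),
                      min_depth = 1L,
                      contigs = NULL,
                      merged = FALSE) {
  sex <- match.arg(sex)
  genotype <- match.arg(genotype)
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  if (!is.data.frame(calls)) stop("'calls' must be a data.frame")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols)) {
    stop("calls is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  calls <- calls[req]
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos)
  calls$strand <- as.character(calls$strand)
  calls$context <- as.character(calls$context)
  calls$n_meth <- as.integer(calls$n_meth)
  calls$n_total <- as.integer(calls$n_total)

  if (nrow(calls)) {
    if (any(calls$n_meth < 0L) || any(calls$n_total < 0L)) {
      stop("negative methylation counts")
    }
    if (any(calls$n_meth > calls$n_total)) {
      stop("n_meth exceeds n_total")
    }
    if (!all(calls$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (!all(calls$context %in% VALID_CONTEXTS)) {
      stop("context must be one of ", paste(VALID_CONTEXTS, collapse = ", "))
    }
    calls <- calls[calls$n_total >= min_depth, , drop = FALSE]
    o <- order(calls$chrom, calls$pos, calls$context, calls$strand)
    calls <- calls[o, , drop = FALSE]
    key <- paste(calls$chrom, calls$pos, calls$context, calls$strand)
    if (anyDuplicated(key)) {
      stop("duplicate calls at identical (chrom, pos, context, strand)")
    }
  }
  calls$level <- ifelse(calls$n_total > 0L, calls$n_meth / calls$n_total,
                        NA_real_)
  rownames(calls) <- NULL

  structure(
    list(sample_id = sample_id, stage = stage, sex = sex,
         genotype = genotype, min_depth = as.integer(min_depth),
         contigs = contigs, merged = isTRUE(merged), calls = calls),
    class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome '%s' (stage %s, %s, %s)\n", x$sample_id,
              x$stage, x$sex, x$genotype))
  cat(sprintf("  %d calls (%d CpG, %d CH), min_depth %d, %s\n",
              nrow(x$calls), sum(x$calls$context == "CG"),
              sum(x$calls$context != "CG"), x$min_depth,
              if (x$merged) "strand-merged" else "stranded"))
  invisible(x)
}

#' Extract the call table of a methylome
#'
#' @param x A \code{methylome}.
#' @param context Optional subset of contexts, e.g. \code{"CG"}.
#' @return The calls data.frame.
#' @export
meth_calls <- function(x, context = NULL) {
  stopifnot(inherits(x, "methylome"))
  calls <- x$calls
  if (!is.null(context)) calls <- calls[calls$context %in% context, , drop = FALSE]
  calls
}

#' Filter a methylome by read depth
#'
#' Retains only calls with \code{n_total >= min_depth}. Filtering is
#' idempotent: re-applying the same threshold is a no-op.
#'
#' @param x A \code{methylome}.
#' @param min_depth Minimum total read count.
#' @return A filtered \code{methylome} with \code{min_depth} updated.
#' @export
filter_depth <- function(x, min_depth) {
  stopifnot(inherits(x, "methylome"))
  x$calls <- x$calls[x$calls$n_total >= min_depth, , drop = FALSE]
  rownames(x$calls) <- NULL
  x$min_depth <- max(x$min_depth, as.integer(min_depth))
  x
}

#' Merge CpG dyads across strands
#'
#' A CpG dyad is a plus-strand cytosine at position \code{p} paired with the
#' minus-strand cytosine at \code{p + 1}. Bulk bisulfite data measure the same
#' dyad on both strands; merging adds the counts of the two calls into a
#' single call at the plus-strand position, which makes per-CpG levels robust
#' to uneven strand coverage. Unpaired CG calls pass through unchanged; CH
#' calls are never merged (a CH site has no symmetric partner).
#'
#' @param x A \code{methylome} with stranded CG calls.
#' @return A \code{methylome} with \code{merged = TRUE} whose CG dyads are
#'   collapsed; total methylated and total read counts per dyad are conserved.
#' @export
merge_cpg_strands <- function(x) {
  stopifnot(inherits(x, "methylome"))
  calls <- x$calls
  cg <- calls[calls$context == "CG", , drop = FALSE]
  ch <- calls[calls$context != "CG", , drop = FALSE]

  if (nrow(cg)) {
    plus <- cg[cg$strand == "+", , drop = FALSE]
    minus <- cg[cg$strand == "-", , drop = FALSE]
    # match each minus-strand C at p+1 to a plus-strand partner at p
    idx <- match(paste(minus$chrom, minus$pos - 1L),
                 paste(plus$chrom, plus$pos))
    paired <- !is.na(idx)
    if (any(paired)) {
      j <- idx[paired]
      plus$n_meth[j] <- plus$n_meth[j] + minus$n_meth[paired]
      plus$n_total[j] <- plus$n_total[j] + minus$n_total[paired]
    }
    cg <- rbind(plus, minus[!paired, , drop = FALSE])
  }
  out <- rbind(cg, ch)
  out$level <- NULL
  # merged dyads may now exceed the stored depth floor only upward, so the
  # original min_depth remains a valid lower bound
  methylome(out, sample_id = x$sample_id, stage = x$stage, sex = x$sex,
            genotype = x$genotype, min_depth = x$min_depth,
            contigs = x$contigs, merged = TRUE)
}

#' Contig lengths of a methylome
#'
#' Returns the declared contig lengths, or infers a lower bound
#' (\code{max(pos) + 2}) per contig when none were declared.
#'
#' @param x A \code{methylome}.
#' @return Named numeric vector of contig lengths.
#' @export
meth_contigs <- function(x) {
  stopifnot(inherits(x, "methylome"))
  if (!is.null(x$contigs)) return(x$contigs)
  if (!nrow(x$calls)) stop("methylome has no calls and no declared contigs")
  tapply(x$calls$pos, x$calls$chrom, function(p) max(p) + 2L)
}

# internal: calls -> GRanges (1 bp per cytosine)
calls_granges <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos + 1L, width = 1L),
    strand = "*")
}

# internal: region/feature data.frame (0-based half-open) -> GRanges
regions_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = "*")
}
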