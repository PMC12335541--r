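#' Read a per-cytosine methylation call table
#'
#' Parses one of three common bisulfite call dialects into a
#' \code{\link{methylome}}, converting everything to the internal 0-based
#' plus-strand coordinate convention and applying the depth filter on the way
#' in. The dialect is always named explicitly -- bedGraph and Bismark coverage
#' files are visually identical, so auto-detection is deliberately not
#' attempted.
#'
#' Dialects:
#' \describe{
#'   \item{\code{methratio}}{TSV with at least 7 columns: chrom, 1-based
#'     position of the cytosine, strand, context (CG/CA/CC/CT), ratio,
#'     methylated count, total count. The ratio column is ignored; levels are
#'     recomputed from counts.}
#'   \item{\code{bismark_coverage}}{chrom, 1-based start, end, percent
#'     methylation, methylated count, unmethylated count. Context is assumed
#'     CG on the plus strand.}
#'   \item{\code{bedgraph}}{chrom, 0-based start, end, percent methylation.
#'     This dialect carries no read counts, so counts are synthesized at a
#'     nominal depth of \code{min_depth} reads; it is lossy and only suitable
#'     for level-based analyses.}
#' }
#'
#' Lines starting with \code{#}, \code{track} or \code{browser} are skipped,
#' as is a leading header row whose position column is non-numeric.
#'
#' @param path File path.
#' @param dialect One of \code{"methratio"}, \code{"bismark_coverage"},
#'   \code{"bedgraph"}.
#' @param min_depth Calls with fewer total reads are dropped.
#' @param sample_id,stage,sex,genotype,contigs Sample descriptors passed to
#'   \code{\link{methylome}}.
#' @return A \code{\link{methylome}}.
#' @export
read_methylation_table <- function(path,
                                   dialect = c("methratio",
                                               "bismark_coverage",
                                               "bedgraph"),
                                   min_depth = 8L,
                                   sample_id = basename(path),
                                   stage = NA_character_,
                                   sex = "mixed",
                                   genotype = "WT",
                                   contigs = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]

  empty <- methylome(
    data.frame(chrom = character(), pos = integer(), strand = character(),
               context = character(), n_meth = integer(),
               n_total = integer()),
    sample_id = sample_id, stage = stage, sex = sex, genotype = genotype,
    min_depth = min_depth, contigs = contigs)
  if (!length(lines)) return(empty)

  fields <- strsplit(lines, "[ \t]+")
  # tolerate one header row (non-numeric position column)
  pos_col <- 2L
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][pos_col])))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (!length(fields)) return(empty)
  }

  min_cols <- switch(dialect, methratio = 7L, bismark_coverage = 6L,
                     bedgraph = 4L)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- lineno[which(nf < min_cols)[1L]]
    stop(sprintf("malformed row at line %d of %s: expected >= %d fields",
                 bad, path, min_cols))
  }
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop(sprintf("malformed row at line %d of %s: non-numeric %s",
                   lineno[which(is.na(v))[1L]], path, what))
    }
    v
  }

  if (dialect == "methratio") {
    calls <- data.frame(
      chrom = col(1L),
      pos = num(2L, "position") - 1,
      strand = col(3L),
      context = normalize_context(col(4L), path, lineno),
      n_meth = num(6L, "methylated count"),
      n_total = num(7L, "total count"))
  } else if (dialect == "bismark_coverage") {
    calls <- data.frame(
      chrom = col(1L),
      pos = num(2L, "position") - 1,
      strand = "+",
      context = "CG",
      n_meth = num(5L, "methylated count"),
      n_total = num(5L, "methylated count") +
        num(6L, "unmethylated count"))
  } else {
    pct <- num(4L, "methylation percentage")
    if (any(pct < 0 | pct > 100)) {
      stop(sprintf("malformed row at line %d of %s: percentage outside [0, 100]",
                   lineno[which(pct < 0 | pct > 100)[1L]], path))
    }
    calls <- data.frame(
      chrom = col(1L),
      pos = num(2L, "position"),
      strand = "+",
      context = "CG",
      n_meth = round(pct / 100 * min_depth),
      n_total = as.numeric(min_depth))
  }
  if (any(calls$n_meth < 0 | calls$n_total < 0)) {
    stop(sprintf("negative counts at line %d of %s",
                 lineno[which(calls$n_meth < 0 | calls$n_total < 0)[1L]],
                 path))
  }
  methylome(calls, sample_id = sample_id, stage = stage, sex = sex,
            genotype = genotype, min_depth = min_depth, contigs = contigs)
}

# methratio context fields can be 2-mers or longer k-mers centred on the C;
# reduce to the CG/CA/CC/CT dinucleotide class
normalize_context <- function(ctx, path, lineno) {
  ctx <- toupper(ctx)
  long <- nchar(ctx) > 2L & nchar(ctx) %% 2L == 1L
  if (any(long)) {
    mid <- (nchar(ctx[long]) + 1L) %/% 2L
    ctx[long] <- substr(ctx[long], mid, mid + 1L)
  }
  bad <- !ctx %in% VALID_CONTEXTS
  if (any(bad)) {
    stop(sprintf("malformed row at line %d of %s: unknown context '%s'",
                 lineno[which(bad)[1L]], path, ctx[which(bad)[1L]]))
  }
  ctx
}

#' Read a BED annotation file as a feature set
#'
#' Parses BED3+ (whitespace-delimited, 0-based half-open) into a feature
#' table with columns \code{chrom, start, end, name, family, strand}. The
#' family label -- e.g. the RepeatMasker family of a TE copy -- is taken from
#' the column named by \code{family_from}, defaulting to the BED name column;
#' BED3-only rows get name and family \code{"unnamed"}.
#'
#' @param path File path.
#' @param family_from Column index (1-based) to use as the family label, or
#'   \code{NULL} to use the name column.
#' @return A data.frame of class \code{"feature_set"}.
#' @export
read_features_bed <- function(path, family_from = NULL) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) {
    return(feature_set(data.frame(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  family = character(),
                                  strand = character())))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED row at line %d of %s: fewer than 3 fields",
                 lineno[which(nf < 3L)[1L]], path))
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1L))
  }
  start <- suppressWarnings(as.numeric(get(2L)))
  end <- suppressWarnings(as.numeric(get(3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("unparseable coordinates at line %d of %s",
                 lineno[which(is.na(start) | is.na(end))[1L]], path))
  }
  if (any(start >= end)) {
    stop(sprintf("start >= end at line %d of %s",
                 lineno[which(start >= end)[1L]], path))
  }
  name <- get(4L)
  name[is.na(name)] <- "unnamed"
  strand <- get(6L)
  strand[!strand %in% c("+", "-")] <- "*"
  family <- if (is.null(family_from)) name else get(as.integer(family_from))
  family[is.na(family)] <- "unnamed"
  feature_set(data.frame(chrom = get(1L), start = as.integer(start),
                         end = as.integer(end), name = name,
                         family = family, strand = strand))
}

#' Construct a feature set from a data.frame
#'
#' @param df Data.frame with columns \code{chrom, start, end} and optionally
#'   \code{name, family, strand} (0-based half-open intervals).
#' @return The validated data.frame with class \code{"feature_set"}.
#' @export
feature_set <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$name)) df$name <- "unnamed"
  if (is.null(df$family)) df$family <- df$name
  if (is.null(df$strand)) df$strand <- "*"
  df <- df[c("chrom", "start", "end", "name", "family", "strand")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df) && any(df$start >= df$end)) stop("feature start >= end")
  rownames(df) <- NULL
  class(df) <- c("feature_set", "data.frame")
  df
}

#' Write called regions to a BED6+ file
#'
#' Serializes RMRs or DMRs as tab-separated BED with a \code{#}-prefixed
#' header: chrom, start, end, name, score (1000 x mean level, integer),
#' strand, then \code{n_cpg} and \code{mean_level}, and for DMRs the
#' difference, p and q values and direction. Coordinates round-trip exactly
#' through \code{\link{read_features_bed}}.
#'
#' @param regions A data.frame of regions as produced by
#'   \code{\link{call_rmrs}} or \code{\link{call_dmrs}} (may be empty).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_regions_bed <- function(regions, path) {
  is_dmr <- nrow(regions) > 0 && !is.null(regions$diff) && any(!is.na(regions$diff))
  header <- c("#chrom", "start", "end", "name", "score", "strand",
              "n_cpg", "mean_level",
              if (is_dmr) c("diff", "p", "q", "direction"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(regions)) {
    kind <- if (!is.null(regions$kind)) regions$kind else "region"
    body <- data.frame(
      chrom = regions$chrom,
      start = regions$start,
      end = regions$end,
      name = sprintf("%s_%d", kind, seq_len(nrow(regions))),
      score = as.integer(round(1000 * regions$mean_level)),
      strand = ".",
      n_cpg = regions$n_cpg,
      mean_level = sprintf("%.6g", regions$mean_level))
    if (is_dmr) {
      body$diff <- sprintf("%.6g", regions$diff)
      body$p <- sprintf("%.3g", regions$p)
      body$q <- sprintf("%.3g", regions$q)
      body$direction <- regions$direction
    }
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Remove clonal duplicates from bisulfite clone patterns
#'
#' Sanger-sequenced bisulfite clones with identical binary methylation
#' patterns are likely PCR duplicates of the same molecule; only the first
#' occurrence of each distinct pattern is kept, preserving input order.
#'
#' @param patterns Character vector of equal-length strings over
#'   \code{\{0, 1\}}, one per clone, one digit per CpG.
#' @return The deduplicated character vector.
#' @export
dedupe_clone_patterns <- function(patterns) {
  if (!length(patterns)) return(character())
  if (length(unique(nchar(patterns))) != 1L) {
    stop("clone patterns have unequal lengths")
  }
  if (any(grepl("[^01]", patterns))) {
    stop("clone patterns must contain only 0 and 1")
  }
  unique(patterns)
}
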