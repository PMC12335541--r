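# shared fixtures built in code; the default simulation is cached per test
# run because several files exercise it

make_calls <- function(chrom = "chr1", pos, n_meth, n_total,
                       strand = "+", context = "CG") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             strand = rep_len(strand, n), context = rep_len(context, n),
             n_meth = n_meth, n_total = n_total)
}

make_methylome <- function(pos, n_meth, n_total, chrom = "chr1",
                           strand = "+", context = "CG",
                           contigs = c(chr1 = 1000L), merged = TRUE, ...) {
  methylome(make_calls(chrom, pos, n_meth, n_total, strand, context),
            contigs = contigs, merged = merged, ...)
}

# trajectory object from bare levels, for testing the kinetics scores
make_traj <- function(levels, stages = paste0("s", seq_along(levels)),
                      id = "t") {
  structure(data.frame(stage = stages, level = levels,
                       n_cpg = rep(10L, length(levels))),
            class = c("trajectory", "data.frame"),
            target_id = id, summary = "median")
}

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- simulation_config()
    .fixture_cache$sim <- list(cfg = cfg, genome = build_synthetic_genome(cfg))
  }
  .fixture_cache$sim
}

# a small fast genome for unit tests: 200 kb, 8 resistant copies
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- simulation_config(
      contigs = c(chr1 = 2e5),
      te_families = data.frame(
        family = c("IAPEz", "L1Md_old"),
        n_copies = c(8L, 4L), copy_length = c(5000L, 2000L),
        resistant = c(TRUE, FALSE), level = c(0.50, NA)),
      n_delayed_promoters = 5L, n_control_promoters = 5L,
      seed = 99L)
    .fixture_cache$small <- list(cfg = cfg,
                                 genome = build_synthetic_genome(cfg))
  }
  .fixture_cache$small
}

# brute-force RMR oracle: enumerate every window, merge by exhaustive
# pairwise checks, recompute region stats over merged spans
brute_force_rmrs <- function(x, params = analysis_params()) {
  calls <- meth_calls(x, context = "CG")
  contigs <- meth_contigs(x)
  qual <- list()
  for (contig in names(contigs)) {
    len <- as.integer(contigs[[contig]])
    cc <- calls[calls$chrom == contig, , drop = FALSE]
    s <- 0L
    while (s < len) {
      e <- min(s + params$window_size, len)
      lv <- cc$level[cc$pos >= s & cc$pos < e]
      if (length(lv) >= params$min_cpgs_per_window &&
          mean(lv) > params$rmr_min_level) {
        qual[[length(qual) + 1L]] <- data.frame(chrom = contig,
                                                start = s, end = e)
      }
      s <- s + params$window_step
    }
  }
  if (!length(qual)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      mean_level = numeric(), kind = character()))
  }
  reg <- do.call(rbind, qual)
  # exhaustive pairwise merge of overlapping/book-ended intervals
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(reg)) {
      j <- i + 1L
      while (j <= nrow(reg)) {
        if (reg$chrom[i] == reg$chrom[j] &&
            reg$start[i] <= reg$end[j] && reg$start[j] <= reg$end[i]) {
          reg$start[i] <- min(reg$start[i], reg$start[j])
          reg$end[i] <- max(reg$end[i], reg$end[j])
          reg <- reg[-j, , drop = FALSE]
          merged_any <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  reg$n_cpg <- NA_integer_
  reg$mean_level <- NA_real_
  for (i in seq_len(nrow(reg))) {
    lv <- calls$level[calls$chrom == reg$chrom[i] &
                        calls$pos >= reg$start[i] & calls$pos < reg$end[i]]
    reg$n_cpg[i] <- length(lv)
    reg$mean_level[i] <- mean(lv)
  }
  reg$kind <- "RMR"
  rownames(reg) <- NULL
  reg
}

# random small methylome on one contig with clustered high-methylation blocks
random_small_methylome <- function(seed, max_len = 50000L) {
  set.seed(seed)
  len <- sample.int(max_len - 5000L, 1L) + 5000L
  n <- round(len / 60)
  pos <- sort(sample.int(len - 2L, n))
  pos <- pos[c(TRUE, diff(pos) >= 2L)]
  # blocks of elevated methylation to create borderline windows
  mu <- rep(0.05, length(pos))
  n_blocks <- sample(2:6, 1L)
  for (b in seq_len(n_blocks)) {
    s <- sample.int(len, 1L)
    w <- sample(300:3000, 1L)
    mu[pos >= s & pos < s + w] <- stats::runif(1, 0.2, 0.8)
  }
  depth <- pmax(8L, stats::rpois(length(pos), 20))
  make_methylome(pos = pos, n_meth = stats::rbinom(length(pos), depth, mu),
                 n_total = depth, contigs = c(chr1 = len))
}

gr_of <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}
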