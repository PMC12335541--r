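test_that("sliding windows report CpG counts and unweighted means", {
  m <- make_methylome(pos = c(10L, 120L, 240L, 360L, 480L),
                      n_meth = c(10L, 8L, 6L, 2L, 0L),
                      n_total = rep(10L, 5), contigs = c(chr1 = 1000L))
  w <- scan_windows(m)
  w1 <- w[w$start == 0L, ]
  expect_equal(w1$end, 500L)
  expect_equal(w1$n_cpg, 5L)
  expect_equal(w1$mean_level, 0.52)
  expect_true(w1$eligible)
  w2 <- w[w$start == 250L, ]
  expect_equal(w2$n_cpg, 2L)
  expect_false(w2$eligible)
  # windows tile from 0 with the configured step and clip at the contig end
  expect_equal(w$start, seq(0L, 750L, by = 250L))
  expect_equal(w$end[w$start == 750L], 1000L)
})

test_that("windows on an empty methylome are all ineligible", {
  m <- methylome(make_calls(pos = integer(), n_meth = integer(),
                            n_total = integer())[0, ],
                 contigs = c(chr1 = 1000L), merged = TRUE)
  w <- scan_windows(m)
  expect_true(all(w$n_cpg == 0L))
  expect_false(any(w$eligible))
})

test_that("stranded input is rejected with advice to merge", {
  m <- make_methylome(pos = 10L, n_meth = 1L, n_total = 10L, merged = FALSE)
  expect_error(scan_windows(m), "merge_cpg_strands")
})

test_that("qualifying windows merge into RMRs with recomputed statistics", {
  # CpGs dense enough that windows [0,500) and [250,750) both qualify,
  # while [500,1000) has no CpGs at all
  pos <- as.integer(seq(10, 490, by = 60))
  m <- make_methylome(pos = pos, n_meth = rep(5L, length(pos)),
                      n_total = rep(10L, length(pos)),
                      contigs = c(chr1 = 2000L))
  r <- call_rmrs(scan_windows(m), m)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 0L)
  expect_equal(r$end, 750L)
  expect_equal(r$n_cpg, length(pos))
  expect_equal(r$mean_level, 0.5)
  expect_equal(r$kind, "RMR")
})

test_that("the residual-methylation threshold is strictly greater-than", {
  pos <- c(10L, 110L, 210L, 310L)
  at_threshold <- make_methylome(pos = pos, n_meth = rep(3L, 4),
                                 n_total = rep(10L, 4),
                                 contigs = c(chr1 = 500L))
  expect_equal(nrow(call_rmrs(scan_windows(at_threshold), at_threshold)), 0L)
  above <- make_methylome(pos = pos, n_meth = c(3L, 3L, 3L, 4L),
                          n_total = rep(10L, 4), contigs = c(chr1 = 500L))
  expect_equal(nrow(call_rmrs(scan_windows(above), above)), 1L)
})

test_that("RMR calling matches the brute-force oracle on small contigs", {
  for (seed in 1:6) {
    m <- random_small_methylome(seed)
    fast <- call_rmrs(scan_windows(m), m)
    slow <- brute_force_rmrs(m)
    expect_equal(fast$start, slow$start, label = sprintf("seed %d", seed))
    expect_equal(fast$end, slow$end)
    expect_equal(fast$n_cpg, slow$n_cpg)
    expect_equal(fast$mean_level, slow$mean_level, tolerance = 1e-12)
  }
})

test_that("every called RMR satisfies the calling criteria", {
  p <- analysis_params()
  for (seed in 7:9) {
    m <- random_small_methylome(seed)
    w <- scan_windows(m, p)
    r <- call_rmrs(w, m, p)
    if (!nrow(r)) next
    expect_true(all(r$n_cpg >= p$min_cpgs_per_window))
    # at least one constituent window above the level threshold
    for (i in seq_len(nrow(r))) {
      inside <- w$start < r$end[i] & w$end > r$start[i] & w$eligible &
        !is.na(w$mean_level)
      expect_true(any(w$mean_level[inside] > p$rmr_min_level))
    }
  }
})

test_that("common CpGs between region sets use AND membership", {
  m <- make_methylome(pos = c(20L, 60L, 120L), n_meth = c(1L, 1L, 1L),
                      n_total = rep(10L, 3), contigs = c(chr1 = 1000L))
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  expect_equal(intersect_rmr_cpgs(a, b, m)$pos, 60L)
  # disjoint sets share nothing
  far <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(nrow(intersect_rmr_cpgs(a, far, m)), 0L)
  # identical sets return every covered CpG inside
  expect_equal(intersect_rmr_cpgs(a, a, m)$pos, c(20L, 60L))
})

test_that("venn overlap counts each side separately", {
  a <- data.frame(chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L))
  b <- data.frame(chrom = "chr1", start = 250L, end = 400L)
  expect_equal(venn_overlap(a, b),
               list(a_only = 1L, shared_a = 1L, shared_b = 1L, b_only = 0L))
  expect_equal(venn_overlap(a, a),
               list(a_only = 0L, shared_a = 2L, shared_b = 2L, b_only = 0L))
  expect_equal(venn_overlap(a, a[0, ]),
               list(a_only = 2L, shared_a = 0L, shared_b = 0L, b_only = 0L))
})

test_that("planted resistant copies are recovered on synthetic data", {
  s <- small_sim()
  m <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "WT", "female",
                                seed = 21)
  r <- call_rmrs(scan_windows(m), m)
  rec <- rmr_recovery(r, s$genome$features[
    s$genome$features$compartment == "resistant_te", ])
  expect_gte(rec$sensitivity, 0.9)
  expect_gte(rec$precision, 0.9)
  # full knockout erases every region
  ko <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "Uhrf2KO",
                                 "female", seed = 22)
  expect_equal(nrow(call_rmrs(scan_windows(ko), ko)), 0L)
})
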