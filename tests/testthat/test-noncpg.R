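test_that("CH site table summarizes per context and excludes CpG", {
  calls <- rbind(
    make_calls(pos = 10L, n_meth = 6L, n_total = 100L, context = "CA"),
    make_calls(pos = 20L, n_meth = 4L, n_total = 100L, context = "CA"),
    make_calls(pos = 30L, n_meth = 1L, n_total = 100L, context = "CT"),
    make_calls(pos = 40L, n_meth = 50L, n_total = 100L, context = "CG"))
  m <- methylome(calls, contigs = c(chr1 = 100L), merged = TRUE)
  ch <- ch_site_table(m)
  expect_equal(nrow(ch), 3L)
  s <- attr(ch, "summary")
  expect_equal(s$mean_level[s$context == "CA"], 0.05)
  expect_equal(s$n_sites[s$context == "CA"], 2L)
  expect_equal(s$mean_level[s$context == "CT"], 0.01)
  # CpG-only input is empty with a warning
  cg_only <- make_methylome(pos = 1L, n_meth = 1L, n_total = 10L)
  expect_warning(empty <- ch_site_table(cg_only), "no CH")
  expect_equal(nrow(empty), 0L)
})

test_that("context matrix extracts flanks with strand correction", {
  #            0123456789
  seqs <- c(c1 = "TTCATTAGGC")
  m <- methylome(make_calls(chrom = "c1", pos = 2L, n_meth = 5L,
                            n_total = 10L, context = "CA"),
                 contigs = c(c1 = 10L), merged = TRUE)
  pfm <- context_frequency_matrix(m, seqs, min_level = 0.02, flank = 2L)
  expect_equal(colnames(pfm), c("-2", "-1", "0", "1", "2"))
  expect_equal(unname(pfm["C", "0"]), 1)
  expect_equal(unname(pfm["A", "1"]), 1)   # single CA site: +1 is A
  expect_equal(unname(pfm["T", "-1"]), 1)
  expect_true(all(abs(colSums(pfm) - 1) < 1e-9))

  # two sites with contexts CA and CT split offset +1 evenly
  m2 <- methylome(rbind(
    make_calls(chrom = "c1", pos = 2L, n_meth = 5L, n_total = 10L,
               context = "CA"),
    make_calls(chrom = "c1", pos = 7L, n_meth = 5L, n_total = 10L,
               context = "CT", strand = "-")),
    contigs = c(c1 = 10L), merged = TRUE)
  # minus-strand C at pos 7 ('G' on plus): plus 5' neighbour A -> context CT
  pfm2 <- context_frequency_matrix(m2, seqs, flank = 2L)
  expect_equal(unname(pfm2["A", "1"]), 0.5)
  expect_equal(unname(pfm2["T", "1"]), 0.5)

  # below-threshold sites leave nothing to analyze
  low <- methylome(make_calls(chrom = "c1", pos = 2L, n_meth = 0L,
                              n_total = 10L, context = "CA"),
                   contigs = c(c1 = 10L), merged = TRUE)
  expect_error(context_frequency_matrix(low, seqs), "no CH sites")
})

test_that("strand flip of genome and calls leaves the matrix unchanged", {
  s <- small_sim()
  cfg <- s$cfg
  m <- simulate_stage_methylome(s$genome, cfg, "E17.5", "WT", "male",
                                seed = 61)
  pfm <- context_frequency_matrix(m, s$genome, flank = 3L)
  # reverse-complement the genome and mirror all calls
  seq1 <- s$genome$sequence[["chr1"]]
  L <- nchar(seq1)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq1), "")[[1]]),
              collapse = "")
  calls <- m$calls
  calls$pos <- L - 1L - calls$pos
  calls$strand <- ifelse(calls$strand == "+", "-", "+")
  m_rc <- methylome(calls, contigs = c(chr1 = L), merged = TRUE)
  pfm_rc <- context_frequency_matrix(m_rc, c(chr1 = rc), flank = 3L)
  expect_equal(pfm, pfm_rc, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("CpA methylation couples to CpG methylation across windows", {
  # deterministic monotone pairing -> rho exactly 1
  n <- 10L
  calls <- rbind(
    make_calls(pos = seq(0L, by = 500L, length.out = n) + 10L,
               n_meth = seq_len(n), n_total = rep(20L, n), context = "CG"),
    make_calls(pos = seq(0L, by = 500L, length.out = n) + 20L,
               n_meth = seq_len(n), n_total = rep(100L, n), context = "CA"))
  m <- methylome(calls, contigs = c(chr1 = 500L * n), merged = TRUE)
  expect_equal(cpa_cpg_coupling(m, 500L)$rho, 1)
  # anti-monotone -> rho exactly -1
  calls$n_meth[calls$context == "CA"] <- rev(seq_len(n))
  m2 <- methylome(calls, contigs = c(chr1 = 500L * n), merged = TRUE)
  expect_equal(cpa_cpg_coupling(m2, 500L)$rho, -1)
  # constant series undefined
  calls$n_meth <- 5L
  m3 <- methylome(calls, contigs = c(chr1 = 500L * n), merged = TRUE)
  expect_warning(r3 <- cpa_cpg_coupling(m3, 500L), "constant")
  expect_true(is.na(r3$rho))
})

test_that("remethylating male methylomes show CpA-dominated CH and coupling", {
  s <- small_sim()
  m <- simulate_stage_methylome(s$genome, s$cfg, "E17.5", "WT", "male",
                                seed = 62)
  ch <- ch_site_table(m)
  pass <- ch[ch$level > 0.02, ]
  expect_gt(mean(pass$context == "CA"), 0.8)
  expect_gt(cpa_cpg_coupling(m, 500L)$rho, 0.8)
  # female E13.5 has no CH calls at all
  f <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "WT", "female",
                                seed = 63)
  expect_equal(sum(f$calls$context != "CG"), 0L)
})
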