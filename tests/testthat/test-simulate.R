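test_that("true level schedule encodes resistance, erasure and knockouts", {
  cfg <- simulation_config()
  # resistant copies hold their level at the erasure endpoint
  expect_equal(true_level_schedule(cfg, "resistant_te", "E13.5", "WT"), 0.50)
  # full knockout erases resistance
  expect_equal(true_level_schedule(cfg, "resistant_te", "E13.5", "Uhrf2KO"),
               0.03)
  # mosaic knockout is the cell-mixture expectation
  expect_equal(true_level_schedule(cfg, "resistant_te", "E13.5", "Dnmt1cKO"),
               0.7 * 0.03 + 0.3 * 0.50)
  # background erases monotonically to the endpoint
  bg <- vapply(cfg$stages[1:6], function(s)
    true_level_schedule(cfg, "background", s, "WT"), numeric(1))
  expect_true(all(diff(bg) <= 0))
  expect_lt(bg[["E13.5"]], 0.08)
  # delayed promoters lag but reach background at the endpoint
  del <- vapply(cfg$stages[1:6], function(s)
    true_level_schedule(cfg, "delayed_promoter", s, "WT"), numeric(1))
  expect_true(all(del[2:5] >= bg[2:5]))
  expect_equal(del[["E13.5"]], bg[["E13.5"]])
  # male remethylation raises background after the endpoint
  expect_gt(true_level_schedule(cfg, "background", "E17.5", "WT", "male"),
            true_level_schedule(cfg, "background", "E17.5", "WT", "female"))
  expect_error(true_level_schedule(cfg, "nope", "E13.5"), "compartment")
  expect_error(true_level_schedule(cfg, "background", "E99"), "stage")
})

test_that("synthetic genome is deterministic, disjoint and in bounds", {
  s <- small_sim()
  g <- s$genome
  f <- g$features
  expect_true(all(f$start >= 0 & f$end <= s$cfg$contigs[f$chrom]))
  o <- order(f$start)
  expect_true(all(f$start[o][-1] >= f$end[o][-nrow(f)]))  # disjoint
  # CpG sites really are CG dinucleotides in the emitted sequence
  seq1 <- g$sequence[["chr1"]]
  expect_true(all(substr(rep(seq1, nrow(g$sites)),
                         g$sites$pos + 1L, g$sites$pos + 2L) == "CG"))
  # CGI promoters are CpG-dense: >= 1 CpG per 20 bp
  prom <- f[f$compartment == "control_promoter", ][1, ]
  n_in <- sum(g$sites$pos >= prom$start & g$sites$pos < prom$end)
  expect_gte(n_in, (prom$end - prom$start) / 20)
  # determinism
  g2 <- build_synthetic_genome(s$cfg)
  expect_identical(g$sequence, g2$sequence)
  expect_identical(g$sites, g2$sites)
  # zero TE copies -> only promoters
  cfg0 <- simulation_config(
    contigs = c(chr1 = 1e5),
    te_families = data.frame(family = character(), n_copies = integer(),
                             copy_length = integer(), resistant = logical(),
                             level = numeric()),
    n_delayed_promoters = 3L, n_control_promoters = 3L)
  g0 <- build_synthetic_genome(cfg0)
  expect_true(all(grepl("promoter", g0$features$compartment)))
  # infeasible packing
  expect_error(build_synthetic_genome(simulation_config(
    contigs = c(chr1 = 1e5),
    te_families = data.frame(family = "IAP", n_copies = 30L,
                             copy_length = 5000L, resistant = TRUE,
                             level = 0.5))), "infeasible")
})

test_that("simulated methylomes are seeded, depth-filtered and unbiased", {
  s <- small_sim()
  m1 <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "WT", "female",
                                 seed = 7)
  m2 <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "WT", "female",
                                 seed = 7)
  expect_identical(m1$calls, m2$calls)
  expect_true(all(m1$calls$n_total >= s$cfg$min_depth))

  # zero coverage -> empty
  cfg0 <- s$cfg; cfg0$coverage_mean <- 0
  m0 <- simulate_stage_methylome(s$genome, cfg0, "E13.5", "WT", "female")
  expect_equal(nrow(m0$calls), 0L)

  # law of large numbers: at huge, near-uniform depth every site converges
  # to its truth (overdispersed depth would leave a heavy low-depth tail)
  cfgh <- s$cfg; cfgh$coverage_mean <- 1e5; cfgh$coverage_dispersion <- 100
  mh <- simulate_stage_methylome(s$genome, cfgh, "E13.5", "WT", "female",
                                 seed = 3)
  truth <- attr(mh, "truth")
  expect_true(all(abs(mh$calls$level - truth$mu) <= 0.01 + 1e-12))
})

test_that("compartment means recover the schedule within two points", {
  s <- default_sim()
  for (st in c("E9.5", "E13.5")) {
    m <- simulate_stage_methylome(s$genome, s$cfg, st, "WT", "female",
                                  seed = 11)
    truth <- attr(m, "truth")
    obs <- tapply(m$calls$level, truth$compartment, mean)
    mu <- tapply(truth$mu, truth$compartment, mean)
    expect_true(all(abs(obs - mu) <= 0.02),
                label = sprintf("stage %s compartment means", st))
  }
})

test_that("mosaic knockout compartment mean follows the mixture law", {
  s <- default_sim()
  m <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "Dnmt1cKO",
                                "female", seed = 13)
  truth <- attr(m, "truth")
  res <- truth$compartment == "resistant_te"
  eff <- s$cfg$mixture_efficiency
  expected <- eff * s$cfg$ko_level + (1 - eff) * s$cfg$m_res
  expect_lt(abs(mean(m$calls$level[res]) - expected), 0.01)
})

test_that("wild-type background erases monotonically across stages", {
  s <- small_sim()
  stages <- s$cfg$stages[1:6]
  means <- vapply(seq_along(stages), function(i) {
    m <- simulate_stage_methylome(s$genome, s$cfg, stages[i], "WT", "female",
                                  seed = 100 + i)
    truth <- attr(m, "truth")
    mean(m$calls$level[truth$compartment == "background"])
  }, numeric(1))
  expect_true(all(diff(means) <= 0.02))  # non-increasing up to noise
})

test_that("RRBS mask keeps calls only in size-selected MspI fragments", {
  # hand-built sequence: CCGG at 0-based 0, 200, 800 -> cuts at 1, 201, 801
  seqs <- c(chrX = paste0(
    "CCGG", strrep("AT", 98), "CCGG", strrep("AT", 298), "CCGG",
    strrep("AT", 50)))
  m <- make_methylome(pos = c(50L, 500L, 950L), n_meth = c(1L, 1L, 1L),
                      n_total = c(10L, 10L, 10L), chrom = "chrX",
                      contigs = c(chrX = nchar(seqs)))
  kept <- apply_rrbs_mask(m, seqs, fragment_min = 150L, fragment_max = 400L)
  expect_equal(kept$calls$pos, 50L)     # fragment [1,201) length 200 kept
  # beyond the last cut -> dropped even with wide bounds
  wide <- apply_rrbs_mask(m, seqs, fragment_min = 1L, fragment_max = 10000L)
  expect_false(950L %in% wide$calls$pos)
  # non-positive min with infinite max disables the mask
  ident <- apply_rrbs_mask(m, seqs, fragment_min = 0L, fragment_max = Inf)
  expect_equal(ident$calls, m$calls)
  # no CCGG anywhere -> empty with warning
  expect_warning(
    none <- apply_rrbs_mask(m, c(chrX = strrep("AT", 600)), 150L, 400L),
    "no CCGG")
  expect_equal(nrow(none$calls), 0L)
})

test_that("simulation artifacts round-trip through the writers", {
  s <- small_sim()
  m <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "WT", "female",
                                seed = 5)
  out <- withr::local_tempdir()
  write_simulation(s$genome, list(e13 = m), out)
  back <- read_methylation_table(file.path(out, "e13.meth.tsv"), "methratio",
                                 min_depth = s$cfg$min_depth,
                                 contigs = s$cfg$contigs)
  expect_equal(back$calls$pos, m$calls$pos)
  expect_equal(back$calls$n_meth, m$calls$n_meth)
  expect_equal(back$calls$n_total, m$calls$n_total)
  fa <- Biostrings::readDNAStringSet(file.path(out, "genome.fa"))
  expect_equal(as.character(fa[["chr1"]]), s$genome$sequence[["chr1"]])
})
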