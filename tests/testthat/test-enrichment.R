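test_that("region shuffling preserves lengths, bounds and determinism", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(0L, 500L, 10L), end = c(100L, 750L, 60L))
  contigs <- c(chr1 = 10000, chr2 = 500)
  s1 <- shuffle_regions(regions, contigs, seed = 5)
  s2 <- shuffle_regions(regions, contigs, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sort(s1$end - s1$start), sort(regions$end - regions$start))
  expect_equal(s1$chrom, regions$chrom)
  expect_true(all(s1$start >= 0 & s1$end <= contigs[s1$chrom]))
  expect_error(shuffle_regions(data.frame(chrom = "chr2", start = 0L,
                                          end = 900L), contigs),
               "longer than")
})

test_that("shuffled placements are approximately uniform", {
  one <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  contigs <- c(chr1 = 10000)
  starts <- vapply(1:1000, function(s)
    shuffle_regions(one, contigs, seed = s)$start, numeric(1))
  # sub-integer jitter breaks ties without moving any placement by >=1 bp
  set.seed(1)
  ks <- suppressWarnings(
    stats::ks.test(starts + stats::runif(1000), "punif", 0, 10000 - 99))
  expect_gt(ks$p.value, 0.01)
})

test_that("metaprofile bins signal around centers", {
  contigs <- c(chr1 = 100000)
  # uniform signal -> every bin at that value
  sig <- data.frame(chrom = "chr1", start = 0L, end = 100000L, value = 2)
  centers <- data.frame(chrom = "chr1", pos = c(30000L, 60000L))
  prof <- metaprofile(sig, centers, contigs, flank = 5000L, n_bins = 100L)
  expect_length(prof, 100L)
  expect_true(all(abs(prof - 2) < 1e-9))
  # step signal on the right half of one center
  sig2 <- data.frame(chrom = "chr1", start = 30000L, end = 35000L, value = 1)
  prof2 <- metaprofile(sig2, centers[1, , drop = FALSE], contigs,
                       flank = 5000L, n_bins = 100L)
  expect_true(all(abs(prof2[1:50] - 0) < 1e-9))
  expect_true(all(abs(prof2[51:100] - 1) < 1e-9))
  # bin width is 2*flank/n_bins
  expect_equal(as.integer(names(prof2)[2]) - as.integer(names(prof2)[1]),
               100L)
  # centers truncated by the contig edge are dropped and counted
  near_edge <- data.frame(chrom = "chr1", pos = c(100L, 50000L))
  prof3 <- metaprofile(sig, near_edge, contigs, flank = 5000L)
  expect_equal(attr(prof3, "n_edge_dropped"), 1L)
  expect_error(metaprofile(sig, near_edge[1, , drop = FALSE], contigs,
                           flank = 5000L), "no usable centers")
})

test_that("TE composition counts per family and assigns majorities", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 200L, 400L, 600L),
                        end = c(100L, 300L, 500L, 700L))
  te <- feature_set(data.frame(
    chrom = "chr1", start = c(10L, 210L, 410L, 0L),
    end = c(90L, 290L, 490L, 50L),
    name = c("a1", "a2", "a3", "b1"),
    family = c("IAPEz", "IAPEz", "IAPEz", "L1Md")))
  comp <- te_composition(regions, te)
  per <- comp$per_family
  expect_equal(per$fraction[per$family == "IAPEz"], 0.75)
  expect_equal(per$fraction[per$family == "L1Md"], 0.25)
  expect_equal(per$fraction[per$family == "none"], 0.25)
  # region 1 overlaps both families; majority overlap is IAPEz (80 vs 50)
  excl <- comp$exclusive
  expect_equal(excl$n_regions[excl$family == "IAPEz"], 3L)
  expect_equal(excl$n_regions[excl$family == "L1Md"], 0L)
  expect_equal(sum(excl$fraction), 1)
  # empty TE set -> everything 'none'
  comp0 <- te_composition(regions, te[0, ])
  expect_equal(comp0$per_family$fraction[comp0$per_family$family == "none"],
               1)
})

test_that("hypergeometric overlap matches exact combinatorics", {
  expect_equal(overlap_hypergeometric(10, 5, 5, 5), 1 / 252,
               tolerance = 1e-12)
  expect_equal(overlap_hypergeometric(10, 5, 5, 0), 1)
  expect_error(overlap_hypergeometric(10, 5, 5, 6), "inconsistent")
  # monotone decreasing in the observed overlap
  p <- vapply(0:5, function(k) overlap_hypergeometric(20, 8, 5, k),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("hypergeometric tail equals exhaustive enumeration on small universes", {
  for (N in c(8L, 11L)) {
    for (a in c(2L, 5L, N - 1L)) {
      for (b in c(3L, 6L)) {
        if (b > N) next
        draws <- utils::combn(N, b)
        overlaps <- colSums(draws <= a)   # set A = 1..a
        for (k in 0:min(a, b)) {
          expect_equal(overlap_hypergeometric(N, a, b, k),
                       mean(overlaps >= k), tolerance = 1e-12,
                       label = sprintf("N=%d a=%d b=%d k=%d", N, a, b, k))
        }
      }
    }
  }
})

test_that("empirical p-values use the add-one rule", {
  expect_equal(empirical_pvalue(10, c(1, 2, 3)), 1 / 4)
  expect_equal(empirical_pvalue(0, c(1, 2, 3)), 1)
})

test_that("signal at resistant copies peaks at RMR centers, not at shuffles", {
  s <- default_sim()
  m <- simulate_stage_methylome(s$genome, s$cfg, "E13.5", "WT", "female",
                                seed = 71)
  rmrs <- call_rmrs(scan_windows(m), m)
  res <- s$genome$features[s$genome$features$compartment == "resistant_te", ]
  sig <- data.frame(chrom = res$chrom, start = res$start, end = res$end,
                    value = 1)
  genomic_mean <- sum(res$end - res$start) / sum(s$cfg$contigs)
  prof <- metaprofile(sig, rmrs, s$cfg$contigs, flank = 5000L,
                      n_bins = 100L)
  expect_gte(mean(prof[c(50, 51)]) / genomic_mean, 5)
  # pooled shuffled centers are flat
  shuf <- do.call(rbind, lapply(1:20, function(k)
    shuffle_regions(rmrs, s$cfg$contigs, seed = k)))
  prof0 <- metaprofile(sig, shuf, s$cfg$contigs, flank = 5000L,
                       n_bins = 100L)
  expect_lt(max(prof0) / genomic_mean, 2)
})
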