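# rmrtools

Analysis toolkit for **residual DNA methylation during germline epigenetic
reprogramming**. Mouse primordial germ cells (PGCs) erase almost all of
their 5mC between E10.5 and E13.5, but a minority of sequences — chiefly
evolutionarily young retrotransposons such as IAP/ERVK copies — resist
erasure and retain substantial methylation, while some CpG-island promoters
(e.g. of germline genes) demethylate with delayed kinetics. `rmrtools`
implements the window-based analyses used to characterize this biology from
per-cytosine bisulfite call tables, and ships a seeded methylome simulator
so the whole pipeline is testable end to end without any external data.

For epigenomics analysts working with RRBS/WGBS call tables (methratio,
Bismark coverage, bedGraph) who need region-level statements: where does
methylation persist, which TE families carry it, how does a knockout change
it, and is the persistence statistically real.

## What it computes

**Residually methylated regions (RMRs).** Each contig is tiled with
sliding windows (width *w* = 500 bp, offset *s* = 250 bp). For window *W*
with covered CpGs *i* = 1..*n*, the level is the unweighted CpG mean
*m̄(W) = (1/n) Σ mᵢ* with *mᵢ = meth reads / total reads*. A window
qualifies when *n ≥ 4* and *m̄ > 0.30*; qualifying windows that overlap or
are book-ended merge into one RMR whose statistics are recomputed over the
merged span.

**Differential methylation (DMRs).** For two samples A and B, every window
with ≥ 4 CpGs covered in both is tested: Δ = *m̄_B − m̄_A* (unweighted CpG
means) and a two-sided exact test on the pooled 2×2 table
(sample × methylated/unmethylated read counts), with Benjamini–Hochberg
correction across all tested windows. A DMR requires |Δ| > 0.20 and
*q* < 0.01.

**Erasure kinetics.** Reference CpGs are those > 50% methylated in
epiblast and < 20% in E13.5 PGCs; stage-ordered trajectories (median per
stage) are compared by a delay score *D* (mean intermediate-stage excess
over the reference trajectory), classifying each target as *erased*,
*delayed* (*D* > 0.15 and erased endpoint) or *resistant* (endpoint
≥ 30%).

**Non-CpG methylation.** CH context tables, sequence-context frequency
matrices of CH sites > 2% methylated (logo-ready, strand-corrected), and
the Spearman coupling between window-level CpA and CpG methylation that
characterizes remethylating prospermatogonia.

**Enrichment.** Length-preserving within-contig region shuffles, binned
signal metaprofiles in ±5 kb around region centers, TE-family composition
of region sets, and upper-tail hypergeometric overlap tests.

**Simulator.** A synthetic genome (default one 2 Mb contig) with planted
resistant/non-resistant TE copies, delayed and control CGI promoters and
Poisson-spaced background CpGs; per-stage true levels follow a monotone
erasure schedule with male remethylation; reads are sampled binomially
under negative-binomial depth; knockouts erase TE resistance fully
(`Uhrf2KO`) or as a mosaic cell mixture (`Dnmt1cKO`). Ground truth is
attached to every simulated methylome.

## Worked example

```r
library(rmrtools)

cfg <- simulation_config(contigs = c(chr1 = 5e5), seed = 42,
                         te_families = data.frame(
                           family = c("IAPEz", "L1Md_old"),
                           n_copies = c(12L, 8L), copy_length = c(5000L, 2000L),
                           resistant = c(TRUE, FALSE), level = c(0.50, NA)))
genome <- build_synthetic_genome(cfg)
pgc <- simulate_stage_methylome(genome, cfg, "E13.5", "WT", "female", seed = 42)
pgc
#> methylome 'E13.5_female_WT' (stage E13.5, female, WT)
#>   7969 calls (7969 CpG, 0 CH), min_depth 8, strand-merged

rmrs <- call_rmrs(scan_windows(pgc), pgc)
head(rmrs, 3)
#>   chrom start   end n_cpg mean_level kind
#> 1  chr1 46000 51250   125  0.4907378  RMR
#> 2  chr1 54250 59500   122  0.4933997  RMR
#> 3  chr1 61250 66500   121  0.5005922  RMR

aggregate_by_feature(pgc, genome$features, group_by = "family")
#>              group mean_level n_cpg n_copies_covered n_copies_total
#> 1 delayed_promoter 0.05275954  1419               30             30
#> 2 control_promoter 0.02127374  1417               30             30
#> 3         L1Md_old 0.04912327   380                8              8
#> 4            IAPEz 0.50337296  1419               12             12

ko <- simulate_stage_methylome(genome, cfg, "E13.5", "Uhrf2KO", "female", seed = 43)
dmrs <- call_dmrs(pgc, ko)
nrow(dmrs); mean(dmrs$diff)
#> [1] 12
#> [1] -0.457
```

Twelve RMRs are called — one per planted resistant IAPEz copy — at ~50%
methylation against a ~5% background, while the erased background,
promoters and non-resistant L1Md copies stay below threshold. The
knockout contrast recovers each resistant copy as a hypomethylated DMR
with a mean loss near the scheduled 0.47.

`run_pipeline(config, seed, outdir)` chains
simulate → RMR → kinetics → DMR → non-CpG → enrichment from a single YAML
config and writes BED/TSV outputs plus a `summary.json`;
`inst/scripts/run-pipeline.R` wraps it for shell use.

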