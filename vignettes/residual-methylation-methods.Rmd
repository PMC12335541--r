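---
title: "Methods: residual methylation analysis and the methylome simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual methylation analysis and the methylome simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmrtools)
```

This vignette is the package's account of its methods: the statistical
model behind each analysis, the parameters that matter and why their
defaults are what they are, what the simulator does and does not emulate,
and the numerical conventions adopted where the analyses left genuine
design freedom.

## The biological setting

Mouse primordial germ cells (PGCs) undergo near-global 5mC erasure between
E10.5 and E13.5. Three behaviours structure the analyses here:

* **erased** sequences follow the genome-wide erasure curve;
* **delayed** sequences (typically CpG-island promoters of germline genes)
  reach full erasure but lag the genome by one or more embryonic stages;
* **resistant** sequences (young retrotransposon copies, IAP/ERVK above
  all) retain on the order of half their methylation at E13.5, dependent
  on the maintenance machinery — a full knockout of that machinery erases
  them, a mosaic conditional knockout attenuates them in proportion to the
  deleted cell fraction.

After E14.5 male germ cells remethylate and additionally gain non-CpG
methylation, mostly in the CpA context and coupled to local CpG levels.

## Coordinate and data conventions

All internal coordinates are 0-based half-open; 1-based input dialects
(methratio, Bismark coverage) are converted on read. Methylation levels
are always recomputed as `n_meth / n_total`, never trusted from a file's
ratio column. CpG dyads are strand-merged by count addition before any
windowed analysis: bulk bisulfite data measure the same dyad on both
strands, and pooling makes per-CpG levels robust to uneven strand
coverage. Merging is an explicit step (`merge_cpg_strands()`) rather than
an assumption about the upstream caller, because methratio can emit either
convention depending on its flags. CH calls are never merged: a CH site
has no symmetric partner.

The depth filter (default 8 reads) is applied at read time and is
idempotent. The bedGraph dialect carries no counts; its rows are given a
nominal depth equal to the filter so they survive it, which makes that
dialect lossy and suitable only for level-based analyses.

## Window statistics and RMR calling

Windows are 500 bp wide at 250 bp offsets, generated per contig from
coordinate 0, with the final partial window evaluated as-is. The window
level is the *unweighted mean of per-CpG levels* — one CpG, one vote —
rather than a read-pooled ratio; pooling is available behind a flag but
the unweighted mean is the default everywhere so that deep CpGs cannot
dominate a window. A window is eligible with at least 4 covered CpGs and
residually methylated when its mean is *strictly* above 30% ("more than
30%" reads as a strict inequality; "at least 4" as a weak one).

Qualifying windows that overlap or are book-ended merge into one RMR
spanning their union, and the region's CpG count and mean are recomputed
over the merged span. Two conventions were genuinely open:

* whether the 30% criterion re-applies to the merged region — we apply it
  at window level only and report the recomputed region mean, so a region
  is documented by what it actually contains;
* whether region coordinates trim to the outermost CpG — the default is
  the union window span, with `trim_to_cpg = TRUE` available, since
  reported average RMR sizes do not disambiguate the convention.

The caller is validated against a brute-force oracle (enumerate every
window, merge by exhaustive pairwise checks) on random small contigs.

## Differential methylation

Candidate units are the same sliding windows restricted to CpGs covered in
both samples. Within a window the per-CpG methylated/unmethylated counts
of each sample are pooled into a 2×2 table and tested with a two-sided
conditional exact test (hypergeometric tail, identical to Fisher's test;
implemented directly so thousands of windows are cheap, and cross-checked
against `fisher.test` in the test suite). Benjamini–Hochberg correction
runs over all tested windows genome-wide. A DMR needs both an effect
(|Δ| > 20 percentage points of unweighted CpG means) and significance
(q < 0.01). Same-direction overlapping windows merge; merged regions
recompute Δ over the span and inherit their best constituent p/q.

Pooling counts within a window is deliberately simple and transparent. It
is conservative under within-window heterogeneity (the pooled null
variance is largest when levels are homogeneous), which the null
calibration test confirms: across 50 replicate pairs simulated from an
identical truth, no replicate reports a DMR and the rejected-window
fraction is far below the nominal q threshold. The package does not try to
reproduce any specific published DMR engine's internals; the three printed
criteria define correctness.

## Kinetics

Reference CpGs for the genome-wide erasure curve must be strictly above
50% in epiblast and strictly below 20% at E13.5 in positions covered in
both samples; resistant sequences fail the second criterion by
construction (≥ 99.6% of resistant-TE CpGs are excluded in simulation).
Trajectories are per-stage medians (mean available), with stage order
taken from the sample sheet, never parsed from labels.

The delay score `D` — the mean intermediate-stage excess of a target
trajectory over the reference — and its threshold `delta = 0.15` are this
package's own formalization of what is otherwise a visual comparison of
erasure curves. `D` is antisymmetric and zero for identical kinetics. The
default `delta` sits between the simulator's delayed-promoter excess
(~0.29 under default schedules) and the background's (~0), separating the
two with margin on either side; it is a labelled invention, not a
published constant. Classification is: resistant if the E13.5 endpoint is
at or above the 30% residual threshold; else delayed if `D > delta` and
the endpoint is below the 20% reference criterion; else erased.

## Non-CpG analysis

CH sites with observed level strictly above 2% enter the sequence-context
matrix; flanks (default ±5, unstated in the source analyses) come from the
genome sequence with minus-strand contexts reverse-complemented so offset
+1 is always 3′ of the methylated C. Matrix columns each sum to 1 and
offset 0 is all-C by construction; the matrix is emitted for logo tools
rather than rendered. Depth filtering beyond the global 8× floor is not
re-applied before the 2% cut. CpA–CpG coupling is the Spearman correlation
of window-level CpA and CpG means over windows containing both.

## Enrichment

Region shuffles are length-preserving and per-contig (placements stay on
the source contig), which preserves contig composition on small synthetic
genomes — a deliberate divergence from shuffling tools that relocate
across chromosomes. Metaprofiles split ±5000 bp around each center into
100 equal bins (bin count configurable; the source analyses do not state
one) and average per-base bedGraph signal, treating absent intervals as
zero and dropping edge-truncated centers with a reported count. Empirical
enrichment p-values use the add-one estimator (r+1)/(n+1). Hypergeometric
overlap tests are upper-tail and validated against exhaustive enumeration
for small universes.

## The simulator: what it emulates

The generator's defaults are the study conditions the analyses assume,
chosen once, mid-range of the reported effect sizes:

| parameter | default | rationale |
|---|---|---|
| genome | one 2 Mb contig | desk-scale stand-in for a genome |
| resistant TEs | 50 copies × 5 kb at level 0.50 | resistant ERV/IAP methylation reported at 40–60% |
| background E13.5 level | 0.05 | whole-genome E13.5 methylation reported at 5–7% |
| epiblast level | 0.75 | pre-erasure somatic-like methylome |
| full-KO resistant level | 0.03 | reported 2–4% residue |
| mosaic deletion efficiency | 0.7 | yields 0.7·0.03 + 0.3·0.50 = 0.171, inside the reported 10–20% |
| coverage | NB(mean 30, size 3) | RRBS-like depth heterogeneity |
| depth filter | 8 | standard RRBS call filter |
| CpA coupling κ | 0.05 | CpA levels are a few percent of local CpG levels |
| delayed-promoter lag | 2 stages | qualitative "delayed kinetics", pinned to full erasure at E13.5 |

True levels follow a monotone per-stage schedule; resistant copies hold
`max(m_res, background)`; delayed promoters follow the background schedule
shifted two stages later during erasure and rejoin it at the endpoint;
control CGI promoters stay at 2% throughout. Male remethylation applies a
per-500 bp-tile uniform(0.4, 1) multiplier to the remethylating
compartments: bulk remethylation is regionally heterogeneous, and this
heterogeneity is what gives window-level summaries non-degenerate variation
(a perfectly flat level would make rank correlations between CpA and CpG
window means meaningless). CH calls appear only in remethylating male
stages; CpA truth is κ times the realized per-tile mean CpG truth, CC/CT
sit at 0.1%. The mosaic knockout is sampled per read from the mixture
level — distributionally identical to drawing each read from a deleted
cell with probability `eff`, matching how bulk bisulfite data arise from a
cell mixture.

**What the simulator does not emulate:** read-level artifacts (no FASTQ,
no alignment error), bisulfite conversion failure (an ε hook is reserved
but defaults to 0), sequence evolution of TE copies (copies are CpG-regular
planted intervals, not diverged repeats), linkage between neighbouring
CpGs beyond compartment structure, replicate-to-replicate biological
variance, and genome-scale CpG landscape realism. Passing tests therefore
demonstrate the *pipeline's* correctness and calibration under a
structurally faithful data-generating model — not that real-genome RMR
counts or sizes would be reproduced; those depend on the real repeat
landscape and on WGBS coverage.

## Numerical choices and degenerate inputs

Strictness of every threshold follows its wording: `> 0.30`, `> 0.50`,
`< 0.20`, `> 0.02` strict; `≥ 4 CpGs` weak. Windows without CpGs have
undefined means and are ineligible rather than zero. Exact-test p-values
use the `dhyper` likelihood-ordering definition with a 1+1e-7 tolerance
factor (the same convention as `fisher.test`); degenerate margins give
p = 1. The RRBS mask keeps calls only in fragments between successive
MspI cut positions (cut = CCGG start + 1) whose length is inside
[150, 400] bp; terminal regions beyond the outermost cuts belong to no
fragment, and a non-positive minimum with infinite maximum disables the
mask entirely. LUMA estimates clip to [0, 1] against assay noise.
Feature aggregation assigns a CpG to every overlapping feature (no
ownership resolution), matching how RepeatMasker-style annotations nest.

## Problem sizes

The packaged tests and the acceptance script run on the default 2 Mb
genome (~27k CpG dyads, ~700k CH sites in remethylating stages) with
50 null DMR replicates, 20 oracle contigs up to 50 kb, replicate kinetics
time courses over six stages, and 100 shuffled region sets for the
enrichment null — sizes chosen so the full suite completes in minutes on
one CPU while leaving every statistical check adequately powered.

## Known limitations

* Exactly two samples per DMR contrast; replicate pooling happens upstream.
* The delay classification needs the full epiblast-to-E13.5 axis; partial
  trajectories error rather than guess.
* bedGraph methylation input is lossy (no counts), and bigWig signal is
  out of scope — convert to bedGraph first.
* The window-pooled exact test trades per-CpG modelling for transparency;
  strongly anti-correlated within-window effects can cancel in Δ.
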