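---
title: "Calling sRNA targets from MAPS coverage: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling sRNA targets from MAPS coverage: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapscall)
```

## The procedure and its assumptions

MAPS (MS2-affinity purification coupled with RNA sequencing) infers the
targets of a small regulatory RNA from a single contrast: coverage in the
pull-down library versus coverage in an untagged control. `mapscall`
implements that inference as a deterministic rule, not a statistical
test, which mirrors how such single-replicate pull-downs are analysed in
practice:

1. **Regions.** Each gene contributes three regions scored independently.
   The 5′ UTR runs from the experimentally determined transcription start
   site (TSS) to the gene start if that distance is at least
   `utr5_min_len` (100 nt); genes without a TSS, or with a shorter
   TSS-derived UTR, get the 100 nt immediately upstream instead (short
   mapped UTRs are unreliable and would otherwise shrink the search
   space for seed-pairing sites). The BODY is the annotated extent. The
   3′ UTR is a fixed 250-nt window from 50 nt inside the 3′ end to
   200 nt downstream — a pragmatic stand-in for unmapped 3′ ends.
   ncRNA features are treated exactly like CDS.
2. **Coverage.** Paired-end stranded alignments are split by SAM flag
   pair (99/147 vs 83/163) into two orientation classes; per-base 1-nt
   coverage from the class matching a region's strand is summed over the
   region and scaled to reads per million (RPM) of the library's total
   aligned fragments. The sum (not the mean) is used, as the region
   definitions fix most lengths; the quantile floor below therefore
   slightly favours long gene bodies, a property inherited from the
   method rather than corrected here.
3. **Calling.** A region is a candidate when
   `log2((ms_rpm + pc)/(control_rpm + pc)) >= 2` — the boundary is
   inclusive, i.e. exactly 4-fold passes — **and** its MS RPM is
   strictly greater than the nearest-rank 25th percentile of MS RPM over
   *all* regions (zeros included). A gene is a candidate when any of its
   regions is.

The rule assumes comparable library composition between pull-down and
control (RPM is the only normalisation), no replicate structure, and a
genome without overlapping genes on the same strand (overlapping
neighbouring *regions* are allowed and scored independently; nothing is
de-overlapped).

Downstream evidence layers are orthodox: one-sided exact binomial tests
for motif presence in candidate 5′ UTRs against sampled background UTRs
and for transcription-factor boxes in gene sets; PWM scanning of both
strands at 70% of the matrix's maximum score with closest-gene
assignment inside a 250-nt promoter window; DEG selection at FDR < 0.01
with no fold-change filter; ChIP coverage averaged over
[ATG−200, ATG+50); and a per-gene matrix fusing all of it.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `utr5_default_len`, `utr5_min_len` | 100 | nt | fallback/minimum 5′ UTR; bacterial UTRs are mostly < 100 nt |
| `utr3_into_gene` + `utr3_downstream` | 50 + 200 | nt | fixed 250-nt 3′ window in the absence of mapped 3′ ends |
| `log2_threshold` | 2 | log2 RPM | 4-fold enrichment; inclusive comparison |
| `coverage_quantile` | 0.25 | fraction | floor against low-coverage ratio artifacts |
| `pseudocount_rpm` | 1 | RPM | keeps zero-control regions finite; set 0 to recover the raw ratio |
| `threshold_fraction` | 0.70 | of max PWM score | site-calling stringency |
| `upstream_window` | 250 | nt | promoter window for site→gene assignment |
| `fdr_threshold` | 0.01 | adjusted p | strict DEG cut, no LFC filter |
| ChIP window | 200 + 50 | nt | promoter occupancy summary |

## What the generator emulates — and what it does not

The synthetic module generates a 200-kb genome with 150 non-overlapping
stranded genes (uniform lengths 300–1500 nt, intergenic gaps ≥ 300 nt so
adjacent planted regions cannot collide), TSSs for 60% of genes at
distances 20–250 nt (exercising both the TSS rule and the fallback),
i.i.d. uniform residues, and libraries of independent per-base Poisson
counts: mean 20 on the sense strand of every gene region, 5% of that on
antisense and intergenic bases (so strand handling is genuinely
exercised), and `baseline × fold` inside planted target regions of the
MS library only. Poisson is the minimal noise model for per-base
fragment counts and keeps closed-form expectations for tests; library
totals are the realised count sums.

Motif presence in 5′ UTRs is *controlled*, not merely inserted: the
configured fractions of foreground and background genes end up with the
motif exactly, chance occurrences elsewhere being scrubbed. This makes
planted enrichment analyses deterministic in `k` and `p0`. PWM
consensus sites are written upstream of chosen genes at chosen offsets;
offsets are kept below `(gap − width)/2` wherever a test asserts
assignment back to the planting gene, because beyond that the nearest
ATG may legitimately belong to a neighbour.

What the generator does **not** emulate: real library-composition biases
(rRNA depletion artifacts, the pull-down's global enrichment of the bait
and its ligands), fragment-length structure, PCR duplicates, overlapping
genes, operonic transcription, or sequence composition bias. Passing the
planted-recovery tests therefore demonstrates that the arithmetic and
strand logic are correct and that the rule behaves as designed under its
own assumptions — not that the thresholds are optimal for any particular
real dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; every reader
  converts at the boundary (GFF3 1-based inclusive, bedGraph 0-based
  half-open, TSS tables 1-based by default via a flag). This removes
  off-by-one drift between modules.
* The quantile floor uses the *nearest-rank* definition (the observed
  value at rank `ceiling(q·n)`) so the floor is always an observed
  coverage; "larger than" is read strictly. The floor is computed on RPM
  over all regions pooled (switchable to raw sums).
* `binomial_upper_tail()` sums tail terms in log space
  (log-sum-exp over `lchoose`), stable for extreme tails; tests pin it
  against exact rational enumeration at small *n* and against
  `binom.test` up to *n* = 200 at 1e−12 relative error.
* PWM windows containing `N` score −∞ and never match. Two threshold
  conventions are provided — `absolute` (0.7 × max score, the default)
  and `minmax` (min + 0.7 × range, useful for log-odds matrices whose
  minimum is negative) — because published scans rarely state which
  scale they used. Count matrices become log-odds against a uniform
  background with a pseudocount of 1.
* Site→gene distance is measured from the site base nearest the ATG;
  exact ties break to the lexicographically smaller gene id, making
  output deterministic.
* Genes shorter than 50 nt get a clipped, `truncated`-flagged 3′ UTR
  rather than being dropped (silent dropping would bias per-gene
  candidacy). Regions running off a linear contig are truncated with a
  flag; circular genomes may wrap.
* The up-regulated percentage rounds half away from zero (208/215 →
  96.74% → 97%). Records with missing adjusted p are never selected —
  the usual convention for independent-filtering output.
* TSS tables must contain at most one TSS per gene; multi-TSS
  resolution is deliberately left to the user rather than silently
  picking one. TSS-derived UTRs are not capped at any maximum length.

## Open design points, resolved

* **Pseudocount.** The published rule is silent about zero-control
  regions; the default adds 1 RPM to both ratio terms, which leaves
  large planted enrichments essentially untouched while keeping every
  ratio finite. Setting it to 0 restores exact depth-rescaling
  invariance (asserted in tests).
* **Floor scale and pooling.** Computed on RPM, pooled across all
  region kinds, as the rule reads most naturally; both choices sit
  behind configuration switches.
* **Orientation protocol.** Which flag class is sense for + strand
  genes is a required configuration item (default `PLUS_SET` ↔ `+`),
  since kit conventions differ.
* **Boundary-behaviour experiment.** The fold-4 test plants only 4
  regions: planting inflates the MS library total, and with many
  planted regions that alone pushes expected log2 ratios measurably
  below 2, turning a boundary-noise experiment into a library-size
  artifact. With 4 small regions the shift is ≈ 0.01 log2 units and
  recovery sits in the expected noise-driven band.

## Problem sizes used by the tests and acceptance script

Simulated recovery runs use the full default conditions (200-kb genome,
150 genes, baseline 20, fold 8, 10 planted UTR5 regions) over 20
replicate library pairs; the null calibration of the motif test uses
1000 repetitions of 40 foreground vs 150 background 100-nt UTRs; oracle
equivalences run on ≤ 5-kb genomes and ≤ 20-region sets where exhaustive
enumeration is exact. The whole suite completes in well under a minute
on one CPU.

## Known limitations

Single-contrast calling cannot separate direct binding from indirect
co-purification; the caller flags enrichment, not interaction. The
region model ignores operons and isoforms, so a 5′ UTR assigned to an
internal operon gene may actually be intra-operonic coding sequence.
The DE stage consumes an externally produced table (the dispersion
model of the upstream DE package is deliberately not re-implemented),
and the integration matrix treats the literature side tables as opaque.
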