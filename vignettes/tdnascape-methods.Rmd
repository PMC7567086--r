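---
title: "Methods: profiling TF binding and chromatin-domain context of tRNA genes"
author: "tdnascape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling TF binding and chromatin-domain context of tRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`tdnascape` profiles tRNA gene (tDNA) loci against multi-cell-line ChIP-seq
peak collections and chromatin-domain annotations. All coordinates live in
`GRanges` (1-based, closed intervals). BED input is 0-based half-open and is
shifted on ingest and shifted back on write, so files round-trip bit-exactly;
GFF3 is 1-based inclusive and is read verbatim; printed browser-style spans
(`chrN:a-b`) are treated as 1-based inclusive. The central containers are

* `TDNASet` — loci with unique ids, optional gene-strand sequences (sequence
  length must equal locus width) and optional structural segmentations
  expressed in locus-relative, gene-orientation coordinates;
* `PeakCollection` — cell line → factor → `GRanges` of peaks;
* `PWMotif` — a 4 × width additive log-odds matrix with a score threshold;
* `GroupAssignment` — per-locus group labels with the per-cell-line mean
  counts that induced them.

Binding is always the *≥ 1 bp overlap* rule. Peaks longer than 1 kb are
removed at ingest (`filterPeaksByLength`, strict `>`), on the grounds that a
single factor is unlikely to occupy a longer footprint.

# Census and classification

`countTfs` counts, per locus and cell line, either distinct bound factors
(`unique`) or (factor, peak) overlap events (`total`). `classifyGroups`
computes per-cell-line arithmetic means over **all** loci (zeros included) and
assigns: Group 1 when the count strictly exceeds the mean in every cell line,
Group 3 when it is zero in every cell line, Group 2 otherwise. The strict
inequality and the all-loci mean are deliberate: the published per-cell
averages are per-tDNA means over the complete locus set, and "more than the
average" reads as a strict comparison. The three groups partition the set by
construction.

Two distance conventions coexist and should not be confused:

* `signedDistance` (locus vs. a single interval, used for the landscape) is
  the edge-to-edge gap with any ≥ 1 bp overlap collapsed to 0, negative
  upstream of the gene, positive downstream; a midpoint distance was rejected
  because a peak covering a multi-hundred-bp cluster would then never score 0.
  One edge case is inherent to half-open/closed interval arithmetic: two
  *abutting* intervals have gap 0 but overlap 0, so "distance 0" is exactly
  "overlap or abutment".
* `nearestBorderDistance` (locus vs. a domain set) is measured from the locus
  **midpoint** to the nearest border of the merged domain set, positive inside
  the domain and negative outside. Midpoints avoid double-counting a ~72-bp
  locus that straddles a border of a domain five orders of magnitude larger.
  Overlapping or book-ended domain records are merged first (`reduce`),
  because only merged-block borders are biologically meaningful boundaries.

# Positional landscape

`distanceLandscape` profiles one cell line in signed, strand-oriented offset
bins over `[-window, +window]`. Bin 0 is the locus body; bin *k* > 0 covers
gap distances `(k−1)·bin + 1 … k·bin` downstream of the gene (mirrored
upstream). Per bin, the statistic is the number of *distinct* factors with a
peak covering any base of the bin, and the 25th/50th/75th percentiles are
taken across loci using linear interpolation between order statistics
(R `quantile` type 7 — conventional and monotone, so the quartile ordering
q25 ≤ q50 ≤ q75 is guaranteed at every offset). Defaults are a 5-kb window
with 25-bp bins: the window spans the few-kb neighbourhood of interest while
the bin still resolves a 72-bp gene body. Whether percentiles are computed
per base or per bin is not canonically fixed; this implementation scores a
factor for a bin if it covers *any* base of it, which at a 25-bp bin is
visually indistinguishable from per-base profiles while being far cheaper.

# PWM scanning and CTCF analysis

`scoreWindow` adds per-position log-odds weights; windows containing a base
outside A/C/G/T are never scored (`NA`) and are skipped by the scanner.
`scanPwm` enumerates every window on both strands; negative-strand ("n") hits
score the reverse complement of the forward window and are reported at the
forward-coordinate window they occupy, with the matched sequence given as
scored. All hits above the strict threshold (default 3.0) are reported —
overlapping hits and multiple hits per locus included, since real loci can
carry several. Raising the threshold can only shrink the hit set (monotone
nesting), and a column-wise reverse-complement-symmetric PWM necessarily
yields mirrored p/n hits of equal score; both properties are tested.

The score is a bare additive log-odds sum with no background-model constant
or pseudocount normalization. External scanners may therefore report scores
shifted by a constant for the same matrix; the package accepts any plain-text
width × 4 matrix (`readPwm`), so a published matrix can be dropped in
unchanged. The PWM shipped in `inst/extdata/ctcf_like_synthetic_pwm.txt` is a
*synthetic* CTCF-flavoured matrix built for validation: its consensus scores
28.385 while random 72-bp sequences exceed 3.0 in ≈ 0.1% of loci, so planted
motifs are recoverable essentially without false positives. Scanning uses the
locus body by default (flanking sequence can simply be included in the
supplied sequences if desired).

`confirmHits` operationalizes "consistent with ChIP-seq data" as ≥ 1 bp
overlap with any CTCF peak in any supplied cell line — the weakest reading,
chosen because no stricter definition is canonical. `assignStructuralRegion`
assigns a hit by its midpoint relative to three landmarks — the midpoints of
the D-loop, anticodon-loop and T-loop spans — giving four regions
(5′–D, D–anticodon, anticodon–T, T–3′) that partition the locus; the variable
loop is folded into anticodon–T. A midpoint exactly on a landmark goes to the
downstream (3′) region; the tie-break is arbitrary but fixed.
`cohesinColocalization` requires every factor of {CTCF, RAD21, SMC3} to
overlap the locus in the *same* cell line, and reports both the ≥ 1-cell-line
set and the all-cell-lines subset; a requested cell line missing a required
factor is a configuration error naming the factor.

# The synthetic-data generator

The generator (`simulateAll`) is first-class, tested code: it emits every
pipeline input with planted structure recorded in a `GroundTruth`, and its
**defaults are the study conditions** the pipeline is validated under —
489 loci of 72 bp, six cell lines with 60 assayed TFs each, group fractions
134/249/106, peak lengths 150–1000 bp, a 129/489 motif-plant fraction, a
20/147 ChIP-confirmation fraction, 17 cohesin-colocalized loci (7 in all cell
lines), DHS/conservation fractions 0.99 (Group 1) and 0.30 (Group 3), and LAD
border offsets from a mixture of uniform 0–30 kb and a point mass at 65 kb
outside the domain. One 100-Mb chromosome holds the loci with a minimum
3-kb gap.

Design choices that make the ground truth *exactly* recoverable:

* **Guard bands.** Background peaks (and background DHS/conservation
  intervals) are rejected within ±1 kb of Group-3 loci (of all loci, for
  tracks), and the minimum locus gap exceeds `guardBand + max peak length`,
  so a peak planted on one locus can never reach a neighbour. "No TFs bound"
  is therefore unambiguous under the ≥ 1 bp rule.
* **Conditioned Group-2 indicators.** Each Group-2 locus's per-cell bound
  indicator vector is resampled until it has at least one bound and at least
  one unbound cell line. An unconditioned Bernoulli would occasionally plant
  an all-bound (Group-1-like) or all-unbound (Group-3-like) pattern, i.e.
  a label inconsistent with the classifier's definition.
* **Reserved factor names.** CTCF, RAD21 and SMC3 never occur in the generic
  TF pool; they are planted only where the truth says so, making the
  triple-colocalization and confirmation subsets exactly recoverable.
* **Shared binding propensity.** Each locus carries a propensity θ shared
  across cell lines (uniform on 0.75 ± 0.20 for Group 1, 0.50 ± 0.20 for
  Group-2 bound cells) and each Group-2 locus a bound-probability *q* (Beta
  with mean 0.4, concentration 0.75 — U-shaped, so loci tend to be
  consistently on or off across cell lines). This is what gives per-locus
  counts their high cross-cell-line correlation, a salient property of the
  real data (reported r = 0.73–0.81); the ranges were derived once from the
  variance decomposition (between-locus variance from labels and θ versus
  within-cell binomial noise) so that r lands in that band while Group-1
  counts still clear the per-cell means with large margin (≥ 0.99 label
  recovery at n = 500).
* **Anchor-based domain construction.** TADs tile the chromosome with 5–20 kb
  gaps; a configurable fraction of Group-1 loci act as anchors, each placed a
  recorded 0–50 kb inside one border of its own TAD, with domain lengths
  (300–800 kb) large enough that the anchored border is always the nearest.
  LADs (500 kb–1.5 Mb) are placed entirely to one side so the anchored locus
  sits a recorded distance *outside* the domain, with a protection margin
  keeping later domains clear. Anchors that cannot be placed without
  violating earlier placements are skipped; the truth records the *realized*
  signed distance of every locus, computed from the emitted intervals, so
  truth and files are consistent by construction.

Sub-generators reseed from `seed` plus a fixed stage offset, so each stage is
individually deterministic and a fixed seed yields byte-identical emitted
files (BED6/GFF3/FASTA/TSV/YAML via `writeSimulation`).

What the generator does **not** emulate: realistic nucleotide composition or
real tRNA sequence/structure covariation, ChIP peak-calling noise and
replicate structure, chromosome-scale heterogeneity of domain sizes, and the
actual ENCODE track semantics. Green tests therefore demonstrate that the
implementation recovers what was planted under the stated conditions — they
validate the operations, not any biological claim about new data. Published
headline counts that depend on the real ENCODE/GtRNAdb/TADKB inputs (e.g.
per-cluster unique/total TF counts or the genome-wide motif total) are
reproducible only by running the same operations on those files.

# Interfaces and the report

Analyses are plain exported functions; `runReport(config, outDir)` chains the
full pipeline on a simulation and writes the TSV bundle — per-locus
unique/total counts, group assignment, per-group factor-frequency tables
(percentages to one decimal, raw counts alongside), the landscape, the motif
table (matched sequence 5′→3′, p/n strand, score, confirmation, structural
region), the cohesin table, TAD/LAD border profiles and the domain/track
summary — plus `manifest.json` with the configuration echo, output checksums
and package version. Thresholds are echoed at startup; outputs under a fixed
seed are checksum-identical; partial outputs are removed on failure.
`readPeakManifest` ingests the tab-separated `cell_line, factor, path`
manifest format, so real peak collections can be swapped in for simulated
ones without code changes.

# Problem sizes and runtime choices

The validation suite runs the generator at n = 60 loci × 3 cell lines for
unit tests and n = 500 loci × 6 cell lines (seeded) for recovery checks;
oracle-equivalence tests use ≥ 1000 random instances per primitive
(per-base overlap sets, all-border scans, naive two-strand window
enumeration, with `Biostrings::PWMscoreStartingAt` as an additional external
oracle for forward scores). These sizes keep the full suite and the
acceptance script within a few minutes on one CPU while leaving the binomial
confidence intervals tight enough to be informative.

# Known limitations

* Replicate ChIP tracks for one factor are treated as one pooled interval set
  per factor name; no per-track weighting.
* tDNA clusters are handled by passing cluster intervals as the locus set;
  there is no automatic clustering of nearby loci.
* No significance testing is attached to the enrichment profiles; the
  analysis is descriptive, as is the original.
* `liftOver` between assemblies, BAM-level processing and TAD calling from
  contact matrices are out of scope; inputs are assumed to be on one assembly
  and already peak/domain-called.
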