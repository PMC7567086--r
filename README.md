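# tdnascape

Chromatin and transcription-factor (TF) binding profiles of human tRNA genes
(tDNAs).

tDNAs are short (~72 bp), multi-copy, Pol III-transcribed loci scattered
across the genome. Beyond encoding tRNAs, a subset of them behaves like
regulatory chromatin: they are bound by dozens of Pol II-associated TFs and
insulator proteins, sit in accessible (DNase-hypersensitive) chromatin, carry
CTCF motifs, colocalize with cohesin, and concentrate near the borders of
topologically associating domains (TADs) and outside lamina-associated
domains (LADs). `tdnascape` is a tested, reusable implementation of the full
analysis that establishes these properties from interval data (BED/GFF
annotation plus per-cell-line, per-factor ChIP-seq peak sets), aimed at
genomics analysts who want to re-run or extend this kind of tDNA census on
their own peak collections — plus a seeded synthetic-data generator that
plants every analysed feature with a known ground truth, so the whole
pipeline is validated end to end without any external download.

## The core statistics

**TF census and three-group classification.** For each tDNA *t* and cell line
*c*, the census counts the distinct factors with at least one peak overlapping
the locus by ≥ 1 bp, giving a count matrix *N(t, c)*. With per-cell-line means
*μ(c) = mean_t N(t, c)*:

* **Group 1** — *N(t, c) > μ(c)* in **every** cell line (broadly,
  above-average bound);
* **Group 3** — *N(t, c) = 0* in **every** cell line (unbound);
* **Group 2** — everything else (cell-selective binding).

**Positional landscape.** Around each locus, signed strand-oriented offsets
(0 = the gene body, negative = upstream) are binned and the 25th/50th/75th
percentiles of the per-position distinct-TF count are taken across loci.

**CTCF motif scan.** Additive log-odds scoring of every window on both
strands, *S(w) = Σ_j W[b_j, j]*, reporting hits with *S > 3.0* (strict), the
matched sequence as scored (reverse-complemented for negative-strand "n"
hits), ChIP confirmation (≥ 1 bp overlap with a CTCF peak in any supplied
cell line), and the tRNA structural region of the hit midpoint (5′–D-loop,
D-loop–anticodon, anticodon–T-loop, T-loop–3′).

**Domain context.** Distance from each locus midpoint to the nearest merged
TAD/LAD border (positive inside, negative outside), per-group border-distance
histograms, within-domain containment fractions, and ≥ 1 bp overlap fractions
with DHS and conserved-element tracks.

## Worked example

```r
library(tdnascape)

cfg <- simConfig(seed = 7, nTdnas = 120, nCellLines = 3, nTfsPerCell = 25,
                 genomeLength = 3e7, nCohesin = 5L, nCohesinAllCells = 2L)
sim <- simulateAll(cfg)          # loci + peaks + TADs/LADs + DHS/conservation

counts <- countTfs(sim$tdnas, sim$peaks)
head(counts, 3)
#>           cell01 cell02 cell03
#> tDNA-0001     12      0     15
#> tDNA-0002     17     19     13
#> tDNA-0003     16     18     17

(groups <- classifyGroups(counts))
#> GroupAssignment over 120 tDNAs: Group 1 = 33 | Group 2 = 61 | Group 3 = 26
#>   per-cell-line mean TF counts: cell01 7.20, cell02 8.78, cell03 8.54
```

Every classified label agrees with the planted one, and the per-locus counts
correlate across cell lines because binding propensity is a property of the
locus:

```r
mean(groupOf(groups) == truthLabels(sim$truth)[names(groupOf(groups))])
#> [1] 1
```

Motif scanning, ChIP confirmation and structural-region assignment:

```r
hits <- scanPwm(sim$pwm, sim$tdnas)
hits <- confirmHits(hits, sim$peaks, tdnas = sim$tdnas)$hits
hits <- assignStructuralRegion(hits, sim$tdnas)
head(hits[, c("tdna_id", "matched", "strand", "score", "chip_confirmed",
              "structural_region")], 3)
#>     tdna_id        matched strand  score chip_confirmed structural_region
#> 1 tDNA-0009 CCACCAGGTGGCAG      p 28.385           TRUE       anticodon-T
#> 2 tDNA-0016 CCACCAGGTGGCAG      n 28.385          FALSE       anticodon-T
#> 3 tDNA-0017 CCACCAGGTGGCAG      p 28.385          FALSE       anticodon-T
```

Cohesin colocalization and domain context for the broadly bound group:

```r
cohesinColocalization(sim$tdnas, sim$peaks)$anyCell
#> [1] "tDNA-0009" "tDNA-0069" "tDNA-0078" "tDNA-0101" "tDNA-0117"

g1 <- sim$tdnas[tdnaIds(sim$tdnas) %in% groupMembers(groups, 1)]
containmentFraction(g1, sim$tads)
#> $percent   93.93939
#> $inside    31
#> $total     33
trackOverlapFraction(g1, sim$conserved)
#> $percent   100
```

The five colocalized loci and the DHS/conservation fractions are exactly the
planted ones (`truthPeaks(sim$truth)$cohesin`, `truthTracks(sim$truth)`).
`runReport(cfg, "out/")` runs all of the above and writes the TSV bundle
(counts, groups, frequency tables, landscape, motif table, cohesin table,
border profiles, domain summary) plus a checksummed run manifest.

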