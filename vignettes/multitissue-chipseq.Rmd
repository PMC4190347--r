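---
title: "Comparing transcription-factor occupancy across tissues with peakshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transcription-factor occupancy across tissues with peakshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakshare)
```

## The analysis

peakshare implements the comparative stage of a multi-tissue ChIP-seq
study of a bHLH transcription factor such as Twist1, which binds E-box
(5'-CANNTG-3') elements and acts with tissue-specific cofactors.  Given
MACS-style peak tables for two or three tissues (for example embryonic
endocardial cushions, limb buds and peripheral nerve sheath tumour cells),
gene models, expressed-gene lists, a genome sequence, candidate cofactor
PWMs and ChIP-qPCR Ct panels, the pipeline produces:

1. a **peak cascade** per tissue: total peaks, peaks whose nearest
   transcriptional start site (TSS) lies within 50 kb, and peaks
   associated with a gene expressed in that tissue;
2. an **exclusive 7-group classification** of peaks by tissue sharing
   (each tissue alone, each pair, and the three-way group), defined by
   fractional interval overlap;
3. **genomic-location distributions** of peak summits (promoter, UTRs,
   coding exon, intron, intergenic);
4. **E-box and cofactor motif content** of peak sequences, including
   E-box/cofactor *modules* — co-occurrences within a fixed spacing
   window — and a shuffle-based enrichment z-score;
5. **ChIP-qPCR fold enrichment** relative to an IgG control with Student
   t-tests on the underlying ddCt values.

## Coordinate conventions

All intervals are carried as `GenomicRanges::GRanges` (1-based, closed),
the standard Bioconductor representation, so `width == end - start + 1`
and the full findOverlaps machinery applies directly.  External formats
are converted at the I/O boundary: MACS-style tables are read as 1-based
inclusive (a `0-based` dialect flag is available), BED export subtracts
one from starts.  Round-tripping a peak set through BED plus its
annotation sidecar is lossless.

## Peak-to-gene association and the filters

Each peak is associated with (up to) two genes: the nearest TSS in each
genomic direction.  Distance is measured from the nearest peak edge and
is 0 whenever the TSS falls inside the peak — any other convention would
understate a direct promoter hit.  The distance filter keeps peaks whose
smaller absolute distance is at most 50,000 bp; the boundary is
inclusive, since "within 50 kb" naturally reads as `<=`.  Distances can
be taken from the input table's two distance columns (`distances =
"table"`, the right mode when reproducing counts from a table produced
with a different gene build) or recomputed from supplied gene models
(`distances = "computed"`).  Whether published tables measure distance to
the TSS or to the gene-body edge is often unstated; exposing both modes
makes the choice explicit rather than silent.

The expression filter keeps a peak when at least one of its two
associated genes is in the tissue's expressed-gene list; matching is
case-insensitive and exact, with no alias resolution, because alias
tables change over time and would make counts irreproducible.  The
deduplicated expressed genes of the surviving peaks are reported
alongside the peak count; neither count bounds the other, since one gene
can own several peaks and one peak two genes.

Summit locations are classified against all genes with precedence
promoter > 5'UTR > 3'UTR > coding exon > intron > intergenic, so that
every peak gets exactly one category and counts partition the set.  The
promoter window is strand-aware, 1,000 bp upstream to 100 bp downstream
of the TSS by default.  No community-wide standard exists for this
window; commercial annotation tools use internal definitions, so the
bounds are ordinary arguments (`promoter_up`, `promoter_down`) rather
than constants.

## Tissue-sharing groups

Two peaks from different tissues are connected when their shared
nucleotides amount to at least 5% of *either* peak (`rule = "either"`).
`bedtools intersect -f 0.05` is asymmetric in its reference set;
published methods rarely state which set was the reference, and the
symmetric rule is the only order-independent choice.  The asymmetric
variants (`"first"`, `"both"`) are provided for reproduction attempts.
The threshold comparison is inclusive (`>=`).

Clusters are the connected components of this graph (via igraph), and a
cluster's group label is exactly the set of tissues present.  Transitive
chaining is deliberate: if an ECC peak overlaps a limb peak and that limb
peak overlaps a PNST peak, all three form one ECC-Limb-PNST cluster even
without a direct ECC-PNST overlap — connected components are the only
choice that induces a partition.  Because the number printed for a
"shared" group depends on what is enumerated, `shared_peak_counts()`
reports three accountings side by side: clusters, member peaks from the
first tissue, and member peaks from the second.

One subtlety is worth knowing: *raising* the overlap threshold always
removes edges, but can *split* one shared cluster into two, so the
cluster count per group is not monotone in the threshold.  The number of
qualifying edges and the number of peaks belonging to any shared cluster
are monotone, and those are the properties the test suite asserts.

## Motif scanning and modules

Peak sequences are extracted after extending peaks by 200 bp on each
side (clamped at chromosome ends), the convention used when searching
for binding-site context around a summit.  E-box scanning uses the IUPAC
consensus CANNTG on both strands; because the pattern is its own reverse
complement, antisense hits coincide positionally with sense hits and are
reported once with strand ".".  An `N` in the sequence never satisfies a
non-N pattern letter.

PWM hits are scored by log2-odds against the matrix's background after
adding a pseudocount, and a window is a hit when its score reaches
`min + rel_threshold * (max - min)` of the achievable score range
(default 0.8), a matrix-similarity-style relative threshold; windows
containing N are skipped.  A module is an E-box occurrence and a cofactor
occurrence on the same scanned sequence with an edge-to-edge gap of at
most 40 bp, inclusive; overlapping occurrences count as gap 0.  "Within
40 bp" could also be read centre-to-centre, so that variant is exposed
as `gap_mode = "center"`.

Proprietary annotation suites report module *z-scores* whose exact
definition is not public; peakshare instead computes an explicitly
defined statistic: the number of sequences carrying at least one module,
compared with the same count on per-sequence mononucleotide shuffles
(length and base composition preserved, seeded).  `|z| >= 2` is the
conventional reporting threshold, and both tails are meaningful — a
negative z says modules are rarer than composition predicts.  Observed
counts never depend on the number of shuffles, and the whole statistic
is bit-reproducible given a seed.

## qPCR enrichment

Per replicate, `dCt = Ct - input_Ct`; per antibody, `ddCt` subtracts the
mean IgG dCt; fold enrichment is `2^(-mean(ddCt))`, so the IgG control
is exactly 1.  Published protocols often leave input normalisation
unstated, so a `"no-input"` dialect sets `input_Ct = 0`; the IgG
subtraction still cancels plate effects, and the fold is unchanged when
a constant is added to all Ct values of a region.  The significance test
is a two-sided, equal-variance Student t between the antibody's and the
IgG's per-replicate ddCt values (Welch via `var_equal = FALSE`), with
documented sentinels for degenerate inputs: identical constant groups
give p = 1, constant groups with different means give p = 0 with a
warning.  The fold uses the mean ddCt and then exponentiates, rather
than averaging per-replicate folds; the two differ under noise and only
one can be the definition.  No multiple-testing correction is applied —
panels are small and regions are chosen a priori.

## What the synthetic generator emulates

`generate_bundle()` builds a complete toy study from one seeded config:

* a random genome (default three 1.8-Mb chromosomes at GC 0.45) with
  evenly slotted gene models — random strand, 2-4 exons, 80% with a CDS —
  and a terminal gene-free region on each chromosome;
* three tissue peak sets of 200 peaks each with peak lengths uniform in
  50-750 bp, organised into clusters realising a designed 7-group count
  vector exactly: clusters of a shared group place near-coincident peaks
  (jitter <= 20 bp) for each member tissue, guard gaps keep different
  clusters from ever overlapping, and a designed fraction of clusters
  (default 0.4) sits more than 50 kb from every TSS so the distance
  filter has true negatives.  The default group design (147/145/160
  single-tissue clusters, 31/16/18 pairwise, 6 three-way) scales the
  sharing ratios reported in multi-tissue Twist1 occupancy studies down
  to desk size while keeping the three-way count at 6;
* planted motifs: per group, a designed fraction of clusters receives a
  CANNTG written into the genome at the cluster centre (defaults echo
  observed E-box content of shared binding regions: 138/205, 7/10, 6/8,
  5/6, and 0.7 for single-tissue groups), and each E-box-planted cluster
  also receives the cofactor consensus at a spacing cycled through
  {0, 20, 40, 41, 100} bp — deliberately straddling the 40-bp window;
* expressed-gene labels per tissue (default fraction 0.5, a typical
  detected-expressed proportion; no study value exists for this knob);
* qPCR panels in biological triplicate where antibody wells receive
  `baseline - log2(fold)` plus Gaussian Ct noise (defaults: an enriched
  region at fold 8 and a null region at fold 1, both at sd 0.2 cycles).

Because the designed counts must be recovered *exactly*, the generator
scrubs incidental motif occurrences from the extended peak regions
before planting: any CANNTG, and any cofactor-PWM window at or above the
scanning threshold, has its bases rewritten from an A/C alphabet (no
E-box or cofactor site can assemble without G/T), iterating until the
region is clean, with planted intervals protected.  The scrubbing
scanner is an independent index-arithmetic implementation, not the
pipeline's own scanner.  Ground truth for the cascade is likewise
computed by the generator's own brute-force nearest-TSS scan rather than
by the pipeline under test.

This design choice has one visible consequence: on synthetic data the
shuffle background contains *more* modules than the observed sequences
(shuffling restores the motif occurrences that scrubbing removed), so
bundle-level enrichment z-scores are negative.  Positive-control
enrichment is therefore demonstrated on short planted fixtures whose
backbones are motif-free.  More generally, the generator emulates the
*geometry and bookkeeping* of real data — overlap structure, distances,
motif spacings, Ct arithmetic — but not its sequence statistics: real
peaks carry background E-boxes, GC heterogeneity, and overlapping
clusters at no guard distance.  Passing recovery tests therefore
validates the pipeline's logic, not peak-calling or biological effect
sizes.

## Problem sizes and numerical choices

The test suite runs most properties on a reduced study (two 250-kb
chromosomes, 16 clusters) and the parameter-recovery check on the full
default study (3 x 200 peaks); the acceptance script uses the full study
plus 2 x 100 seeded qPCR panels for the type-I and power estimates, and
100 shuffles for the enrichment z.  Ties in nearest-gene assignment are
broken by absolute distance, then TSS coordinate, then gene name, so
results are order-independent.  PWM thresholds compare with `>=` so a
planted exact consensus is always a hit at `rel_threshold = 1`.
Percentages in location distributions are exact divisions; an empty peak
set reports zero counts rather than NaN.

## Known limitations

* No significance is attached to overlap counts (no permutation null for
  sharing); the statistic of interest in the source analyses is the
  count itself.
* Mononucleotide shuffles preserve composition but not dinucleotide
  structure; CpG-driven artefacts would require a dinucleotide-preserving
  shuffle, which is deliberately out of scope.
* The qPCR model assumes perfect amplification efficiency (a 2-fold
  change per cycle); standard-curve efficiency correction is not
  implemented.
* `assign_nearest_genes()` is a per-peak scan, adequate for desk-scale
  sets (hundreds of peaks); genome-scale annotation would call for an
  interval tree, which correctness tests do not need.

## A minimal run

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
dir <- tempfile("bundle")
b <- generate_bundle(cfg, dir = dir)
res <- run_pipeline(bundle_config(dir, seed = 1), outdir = tempfile("run"))
res$cascade
res$groups_post
res$ebox
res$qpcr
```
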