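# peakshare

Multi-tissue comparison of transcription-factor ChIP-seq occupancy, in R.

Developmental transcription factors such as Twist1 bind thousands of
genomic sites, yet act very differently in different tissues. A standard
way to dissect this is to ChIP the factor in several tissues, call peaks
with MACS, and then ask three questions: which peaks are close enough to a
gene to plausibly regulate it, which of those genes are actually expressed
in that tissue, and which binding regions are shared between tissues
versus tissue-specific — and, for the shared ones, whether they carry the
factor's own E-box element (5'-CANNTG-3') near a candidate cofactor's
site. peakshare implements that comparative stage as a tested, scriptable
pipeline, together with the ChIP-qPCR statistics used to validate
individual regions.

## What it computes

For tissues *t* with peak sets *P_t* (MACS-style tables):

* **Cascade** — |*P_t*| → peaks with `min(|d_down|, |d_up|) ≤ 50 kb`
  (distance from the nearest peak edge to the nearest TSS in each genomic
  direction, 0 if the TSS is inside the peak; boundary inclusive) →
  peaks with ≥ 1 associated gene in the tissue's expressed-gene list.
* **Sharing groups** — peaks of different tissues are linked when their
  intersection covers ≥ 5% of either peak's nucleotides; connected
  components become clusters labelled by their exact tissue set
  (`ECC-only`, …, `ECC-Limb-PNST`), a partition of all peaks. Shared
  counts are reported as clusters and as member peaks of either tissue,
  since published totals rarely state which was enumerated.
* **Locations** — each summit classified promoter / 5'UTR / 3'UTR /
  coding-exon / intron / intergenic with that precedence (promoter =
  TSS − 1000 … TSS + 100, strand-aware).
* **Motifs and modules** — peaks extended ± 200 bp; CANNTG scanned on
  both strands (reported once, being self-reverse-complementary); PWM
  hits scored by log2-odds with a range-relative threshold
  (`min + 0.8·(max − min)`); a *module* is an E-box and a cofactor hit
  with edge-to-edge gap ≤ 40 bp; enrichment z compares observed
  module-positive sequences with seeded mononucleotide-shuffle
  backgrounds.
* **qPCR** — per replicate ΔCt = Ct − input Ct; ΔΔCt subtracts the mean
  IgG ΔCt; fold = 2^(−mean ΔΔCt) (IgG ≡ 1.0); two-sided equal-variance
  Student t between antibody and IgG ΔΔCt replicates.

A seeded synthetic-data generator (`generate_bundle()`) emits a toy
genome, gene models, three tissue peak sets realising a designed 7-group
structure, planted E-boxes and cofactor sites at controlled spacings,
expression labels and qPCR panels — with the ground truth serialised next
to the data — so the entire pipeline is exercised end to end without any
external download.

## Worked example

```r
library(peakshare)
cfg <- synth_config(seed = 1)            # 3 tissues x 200 peaks, designed sharing
dir <- file.path(tempdir(), "bundle")
generate_bundle(cfg, dir = dir)          # writes FASTA, peak tables, lists, qPCR
res <- run_pipeline(bundle_config(dir, seed = 1, run_enrichment = FALSE))
res$cascade
#>   tissue total within_tss expressed expressed_genes note
#> 1    ECC   200        123        85              99
#> 2   Limb   200        123        85              93
#> 3   PNST   200        116        82              90
res$groups_post
#>           group clusters peaks_total peaks_first peaks_second
#> 1      ECC-only       71          71          71           71
#> 2     Limb-only       73          73          73           73
#> 3     PNST-only       74          74          74           74
#> 4      ECC-Limb        9          18           9            9
#> 5      ECC-PNST        5          10           5            5
#> 6     Limb-PNST        3           6           3            3
#> 7 ECC-Limb-PNST        0           0           0            0
res$qpcr
#>         region_id antibody n_replicates  mean_ddct      fold     t_stat      p_value significant
#> 1 enriched_region      IgG            3  0.0000000 1.0000000         NA           NA          NA
#> 2 enriched_region   target            3 -3.0066009 8.0366873 -15.595405 9.870821e-05        TRUE
#> 4     null_region   target            3  0.2590912 0.8356141   2.908968 4.372331e-02        TRUE
```

Reading the output: of 200 ECC peaks, 123 lie within 50 kb of a TSS and
85 of those sit near one of 99 expressed genes. After the expression
filter, 9 binding-region clusters are shared between ECC and limb while
71 are ECC-specific — the designed tissue-specific majority. The
"enriched" qPCR region designed at fold 8 comes back at 8.04 with
p ≈ 1e-4; note the designed-null region is (falsely) significant at
p = 0.044 for this particular seed — a reminder that a 5%-level test
produces 5%-level false positives, which the acceptance script
quantifies properly over 100 panels.

The group and E-box tables mirror the familiar figure layout of
multi-tissue occupancy studies (Venn counts per sharing group, E-box
content per group, fold-enrichment bars per region), and
`run_pipeline(..., outdir = )` writes `summary.json`, `cascade.tsv`,
`groups.tsv`, `ebox.tsv`, `modules.tsv`, `locations.tsv` and `qpcr.tsv`
with a provenance block (parameters, seed, input checksums).

A thin CLI wrapper is included at `inst/scripts/peakshare`
(`simulate`, `annotate`, `overlap`, `motifs`, `qpcr`, `run-all`, with a
YAML config).

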