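test_that("generators are bit-reproducible given the seed", {
  cfg <- small_config(seed = 3)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  b1 <- generate_bundle(cfg, dir = d1)
  b2 <- generate_bundle(cfg, dir = d2)
  for (f in c("genome.fa", "genes.tsv", "peaks_ECC.tsv", "peaks_Limb.tsv",
              "peaks_PNST.tsv", "expressed_ECC.txt", "qpcr.csv",
              "ground_truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the genome
  b3 <- generate_genome(small_config(seed = 4))
  expect_false(identical(as.character(b3$genome),
                         as.character(b1$genome)))
})

test_that("genome GC content and annotation respect the config", {
  cfg <- synth_config(n_chroms = 1, chrom_length = 1000000, n_genes = 20,
                      gc_content = 0.5, seed = 5)
  gb <- generate_genome(cfg)
  af <- Biostrings::letterFrequency(gb$genome[[1]], c("G", "C"))
  gc <- sum(af) / 1000000
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)
  expect_identical(nrow(gb$genes), 20L)
  expect_identical(anyDuplicated(gb$genes$tss), 0L)

  # gene-free genome is valid
  gb0 <- generate_genome(synth_config(n_chroms = 1, chrom_length = 200000,
                                      n_genes = 0, seed = 5))
  expect_identical(nrow(gb0$genes), 0L)

  # too-dense design errors with advice
  expect_error(
    generate_genome(synth_config(n_chroms = 1, chrom_length = 100000,
                                 n_genes = 50, seed = 5)),
    "chrom_length")
})

test_that("peak sets honour the designed group structure and lengths", {
  cfg <- small_config(seed = 8)
  gb <- generate_genome(cfg)
  ps <- generate_peaksets(cfg, gb)
  expect_identical(
    ps$truth$group_counts[names(cfg$group_design)],
    stats::setNames(as.integer(cfg$group_design), names(cfg$group_design)))
  w <- unlist(lapply(ps$peaksets, GenomicRanges::width))
  expect_true(all(w >= 50 & w <= 750))
  # within-cluster peaks overlap; cross-cluster peaks never do
  asg <- classify_overlap_groups(build_overlap_graph(ps$peaksets),
                                 ps$peaksets)
  by_cluster <- split(asg$cluster_id, ps$truth$peaks$cluster[
    match(asg$peak_id, ps$truth$peaks$peak_id)])
  expect_true(all(vapply(by_cluster,
                         function(x) length(unique(x)) == 1L, TRUE)))
})

test_that("planted module spacings straddle the gap window as designed", {
  cfg <- small_config(seed = 21, module_plant_spacings = c(40L, 41L),
                      ebox_plant_fraction = stats::setNames(
                        rep(1, 7), overlap_group_levels(c("ECC", "Limb", "PNST"))))
  b <- generate_bundle(cfg)
  all_pk <- do.call(c, unname(b$peaksets))
  seqs <- peak_sequences(all_pk, b$genome, extend = 200)
  mods <- find_modules(scan_consensus(seqs),
                       scan_pwm(seqs, default_cofactor_pwms()$RXR_like, 0.8),
                       max_gap = 40)
  pl <- b$truth$planted[!is.na(b$truth$planted$gap), ]
  for (i in seq_len(nrow(pl))) {
    members <- b$truth$peaks$peak_id[b$truth$peaks$cluster == pl$cluster[i]]
    has <- members %in% mods$peak_id
    expect_identical(unique(has), pl$gap[i] <= 40,
                     label = paste("cluster", pl$cluster[i], "gap", pl$gap[i]))
  }
})

test_that("full E-box planting gives fraction one; zero planting none", {
  lv <- overlap_group_levels(c("ECC", "Limb", "PNST"))
  for (frac in c(1, 0)) {
    cfg <- small_config(seed = 31,
                        ebox_plant_fraction = stats::setNames(rep(frac, 7), lv))
    b <- generate_bundle(cfg)
    seqs <- peak_sequences(do.call(c, unname(b$peaksets)), b$genome)
    asg <- classify_overlap_groups(build_overlap_graph(b$peaksets),
                                   b$peaksets)
    es <- ebox_summary(asg, seqs)
    expect_true(all(es$fraction == frac))
  }
})

test_that("expression labelling drives the cascade ground truth", {
  for (frac in c(1, 0)) {
    cfg <- small_config(seed = 41, expressed_fraction = frac)
    b <- generate_bundle(cfg)
    cas <- b$truth$cascade$ECC
    if (frac == 1) expect_identical(cas$expressed, cas$within_50kb)
    else expect_identical(cas$expressed, 0L)
  }
})

test_that("noiseless qPCR panels invert to the designed fold exactly", {
  cfg <- small_config(seed = 51,
                      qpcr_design = data.frame(region_id = "r8",
                                               antibody = "target",
                                               fold = 8, sd = 0))
  qp <- generate_qpcr(cfg)
  fe <- compute_fold_enrichment(qp$table)
  expect_identical(fe$fold[fe$antibody == "target"], 8)
})

test_that("noisy designed folds are recovered within the sampling band", {
  # with Ct noise sd 0.2 and triplicates, mean ddCt has sd
  # 0.2 * sqrt(2/3) ~ 0.163 cycles, so the estimated fold is the designed
  # fold times 2^N(0, 0.163): ~89% of draws land in [4, 6] for fold 5 and
  # essentially all within a factor 1.5
  folds <- vapply(1:60, function(s) {
    cfg <- small_config(seed = 1000 + s,
                        qpcr_design = data.frame(region_id = "r",
                                                 antibody = "target",
                                                 fold = 5, sd = 0.2))
    fe <- compute_fold_enrichment(generate_qpcr(cfg)$table)
    fe$fold[fe$antibody == "target"]
  }, 0)
  expect_true(all(folds > 5 / 1.5 & folds < 5 * 1.5))
  expect_gte(mean(folds > 4 & folds < 6), 0.75)
  expect_equal(median(folds), 5, tolerance = 0.1)
})
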