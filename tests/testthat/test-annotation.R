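simple_genes <- function() {
  gene_models(
    gene = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "-", "+"),
    tss = c(1500L, 9000L, 40000L),
    tx_start = c(1500L, 4000L, 40000L),
    tx_end = c(3500L, 9000L, 46000L),
    exon_starts = list(c(1500L, 2500L), c(4000L, 8000L),
                       c(40000L, 44000L)),
    exon_ends = list(c(1800L, 3500L), c(5000L, 9000L),
                     c(41000L, 46000L)),
    cds_start = c(1600L, 4200L, 40200L),
    cds_end = c(3300L, 8800L, 45500L))
}

test_that("nearest-gene distances are edge-based and signed by direction", {
  genes <- simple_genes()
  pk <- make_peaks("chr1", 1001, 1200, ids = "p1")  # TSS GA at 1500
  a <- assign_nearest_genes(pk, genes)
  down <- a[a$direction == "down", ]
  expect_identical(down$gene, "GA")
  expect_equal(down$signed_distance, 300)  # 1500 - 1200, downstream +

  # TSS inside the peak counts as distance zero in both directions
  pk2 <- make_peaks("chr1", 1400, 1600, ids = "p2")
  a2 <- assign_nearest_genes(pk2, genes)
  expect_true(all(a2$signed_distance[a2$gene == "GA"] == 0))

  # chromosome without genes: no association, a warning
  pk3 <- make_peaks("chr9", 100, 200, ids = "p3")
  expect_warning(a3 <- assign_nearest_genes(pk3, genes), "chr9")
  expect_identical(nrow(a3), 0L)
})

test_that("nearest-gene assignment matches a brute-force search", {
  set.seed(42)
  genes <- gene_models(
    gene = sprintf("g%d", 1:5), chrom = "chr1", strand = "+",
    tss = tsss <- sort(sample(1000:90000, 5)),
    tx_start = tsss, tx_end = tsss + 500L,
    exon_starts = as.list(tsss), exon_ends = as.list(tsss + 500L))
  starts <- sample(1:95000, 20)
  pk <- make_peaks("chr1", starts, starts + 199, ids = sprintf("p%02d", 1:20))
  a <- assign_nearest_genes(pk, genes)
  for (i in seq_along(pk)) {
    s <- starts[i]; e <- starts[i] + 199
    d <- ifelse(tsss >= s & tsss <= e, 0, ifelse(tsss > e, tsss - e, tsss - s))
    down_d <- d[d >= 0]; up_d <- d[d <= 0]
    mine <- a[a$peak_id == sprintf("p%02d", i), ]
    if (length(down_d))
      expect_equal(mine$signed_distance[mine$direction == "down"],
                   down_d[which.min(abs(down_d))])
    if (length(up_d))
      expect_equal(mine$signed_distance[mine$direction == "up"],
                   up_d[which.min(abs(up_d))])
  }
})

test_that("TSS-distance filter keeps the inclusive 50-kb boundary", {
  pk <- make_peaks("chr1", c(1, 1001, 2001), c(500, 1500, 2500),
                   ids = c("at", "over", "none"))
  pk$down_dist <- c(50000, 50001, NA)
  pk$up_dist <- c(NA, -60000, NA)
  kept <- filter_tss_distance(pk)
  expect_identical(kept$peak_id, "at")
  rep <- attr(kept, "tss_filter_report")
  expect_identical(unname(rep["dropped_no_association"]), 1L)
  expect_identical(unname(rep["dropped_distance"]), 1L)

  # an effectively infinite threshold keeps every associated peak
  expect_identical(length(filter_tss_distance(pk, threshold = Inf)), 2L)
})

test_that("a designed fraction of peaks survives the distance filter", {
  set.seed(7)
  n <- 100
  within <- sample(n, 37)
  d <- numeric(n)
  d[within] <- sample(0:50000, 37, replace = TRUE)
  d[-within] <- sample(50001:200000, n - 37, replace = TRUE)
  pk <- make_peaks("chr1", seq(1, by = 1000, length.out = n),
                   seq(500, by = 1000, length.out = n))
  pk$down_dist <- d
  expect_identical(length(filter_tss_distance(pk)), 37L)
})

test_that("expression filter keeps peaks with any expressed nearest gene", {
  genes <- simple_genes()
  pk <- make_peaks("chr1", c(1000, 30000), c(1199, 30199),
                   ids = c("pA", "pB"))
  assoc <- assign_nearest_genes(pk, genes)
  expr <- expression_set("ECC", "Ga")  # case-insensitive match
  res <- filter_by_expression(pk, assoc, expr)
  expect_identical(res$peaks$peak_id, "pA")
  expect_identical(res$genes, "GA")

  none <- filter_by_expression(pk, assoc, expression_set("ECC", "ZZZ"))
  expect_length(none$peaks, 0L)
  expect_warning(
    empty <- filter_by_expression(pk, assoc, expression_set("ECC", character())),
    "empty expression")
  expect_length(empty$peaks, 0L)

  # monotone: expression-filter output is a subset of its input
  expect_true(all(res$peaks$peak_id %in% pk$peak_id))
})

test_that("location calls follow the precedence and promoter window", {
  genes <- simple_genes()
  # summit 500 bp upstream of + strand TSS (GA at 1500) -> promoter
  pk <- make_peaks("chr1", 951, 1050, ids = "prom", summit = 49L)
  expect_identical(as.character(classify_locations(pk, genes)), "promoter")

  # summit in GB's intron (between exons at 5001..7999), outside promoters
  pk2 <- make_peaks("chr1", 6001, 6100, ids = "intr", summit = 50L)
  expect_identical(as.character(classify_locations(pk2, genes)), "intron")

  # far from everything -> intergenic
  pk3 <- make_peaks("chr1", 70000, 70100, ids = "inter", summit = 50L)
  expect_identical(as.character(classify_locations(pk3, genes)), "intergenic")

  # 5'UTR: exonic, before the CDS on a + gene (GA exon 1500-1599 region)
  pk4 <- make_peaks("chr1", 1551, 1560, ids = "utr", summit = 0L)
  # position 1551 is exonic and < cds_start 1600 but also within the
  # promoter window [500, 1599] -> promoter wins by precedence
  expect_identical(as.character(classify_locations(pk4, genes)), "promoter")
  # GC's 5'UTR: exonic positions in [40100, 40199] are past the promoter
  # window (ends 40099) and before cds_start 40200
  pk5 <- make_peaks("chr1", 40141, 40190, ids = "utr2", summit = 9L)
  expect_identical(as.character(classify_locations(pk5, genes)), "5'UTR")
  # and past the CDS end: 3'UTR
  pk6 <- make_peaks("chr1", 45601, 45650, ids = "utr3", summit = 9L)
  expect_identical(as.character(classify_locations(pk6, genes)), "3'UTR")
})

test_that("location calls agree with a brute-force region-membership oracle", {
  genes <- simple_genes()
  set.seed(11)
  starts <- sample(1:60000, 50)
  pk <- make_peaks("chr1", starts, starts + 100, summit = 50L)
  calls <- classify_locations(pk, genes)
  oracle_one <- function(pos) {
    cats <- character()
    for (i in seq_len(nrow(genes))) {
      tss <- genes$tss[i]; strand <- genes$strand[i]
      prom <- if (strand == "+") pos >= tss - 1000 && pos <= tss + 99
              else pos <= tss + 1000 && pos >= tss - 99
      if (prom) cats <- c(cats, "promoter")
      if (pos >= genes$tx_start[i] && pos <= genes$tx_end[i]) {
        inex <- any(pos >= genes$exon_starts[[i]] & pos <= genes$exon_ends[[i]])
        if (!inex) cats <- c(cats, "intron")
        else if (pos < genes$cds_start[i])
          cats <- c(cats, if (strand == "+") "5'UTR" else "3'UTR")
        else if (pos > genes$cds_end[i])
          cats <- c(cats, if (strand == "+") "3'UTR" else "5'UTR")
        else cats <- c(cats, "coding-exon")
      }
    }
    if (!length(cats)) return("intergenic")
    location_levels[min(match(cats, location_levels))]
  }
  expect_identical(as.character(calls),
                   vapply(starts + 50, oracle_one, ""))
})

test_that("location distribution partitions the peak set", {
  genes <- simple_genes()
  set.seed(3)
  starts <- sample(1:60000, 40)
  pk <- make_peaks("chr1", starts, starts + 150, summit = 75L)
  dist <- location_distribution(pk, genes)
  expect_identical(sum(dist$count), 40L)
  expect_equal(sum(dist$percentage), 100, tolerance = 0.01)

  # all-intergenic set
  far <- make_peaks("chr1", 200000 + 1:5 * 1000, 200100 + 1:5 * 1000,
                    summit = 50L)
  dfar <- location_distribution(far, genes)
  expect_equal(dfar$percentage[dfar$category == "intergenic"], 100)

  # empty set: zeros, no division error
  d0 <- location_distribution(pk[0], genes)
  expect_true(all(d0$count == 0) && all(d0$percentage == 0))
})
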