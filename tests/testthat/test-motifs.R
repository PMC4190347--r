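toy_pwm <- function() {
  # sharp 6-bp motif with consensus ACGTAC
  pwm("toy", matrix(c(
    90,  2,  2,  2, 90,  2,
     2, 90,  2,  2,  2, 90,
     4,  4, 90,  2,  4,  4,
     4,  4,  6, 94,  4,  4), nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), NULL)))
}

test_that("E-box consensus scanning finds palindromic hits once", {
  hits <- scan_consensus(c(s1 = "GGCATGTGCC"))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 3L)  # 0-based offset 2
  expect_identical(hits$matched_seq, "CATGTG")
  expect_identical(hits$strand, ".")

  expect_identical(nrow(scan_consensus(c(s = "AAAAAAAA"))), 0L)
  # N in the sequence never matches a non-N pattern letter
  expect_identical(nrow(scan_consensus(c(s = "NANNTGNN"))), 0L)
  expect_identical(scan_consensus(c(s = "GGCANNTGCC"))$start, 3L)
  expect_error(scan_consensus(c(s = "ACGT"), pattern = "CAXXTG"), "IUPAC")
})

test_that("consensus hits equal a regex oracle on both strands", {
  set.seed(101)
  seq1k <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  # palindromic E-box: one strand-"." record per position
  hits <- scan_consensus(c(s = seq1k))
  orc <- oracle_scan_regex(seq1k, "CANNTG")
  expect_identical(hits$start, sort(unique(c(orc$fwd, orc$rev))))

  # non-palindromic pattern: both strands reported separately
  hits2 <- scan_consensus(c(s = seq1k), pattern = "GGATGT")
  orc2 <- oracle_scan_regex(seq1k, "GGATGT")
  expect_identical(hits2$start[hits2$strand == "+"], orc2$fwd)
  # antisense hits are reported at the forward-strand position of the
  # reverse-complement pattern occurrence
  expect_identical(sort(hits2$start[hits2$strand == "-"]), sort(orc2$rev))
})

test_that("sense-only scanning of a palindromic pattern loses nothing", {
  set.seed(77)
  for (k in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    both <- scan_consensus(c(x = s))$start
    orc <- oracle_scan_regex(s, "CANNTG")
    expect_identical(both, orc$fwd)  # sense regex alone finds them all
  }
})

test_that("PWM scanning matches a per-window brute-force oracle", {
  x <- toy_pwm()
  set.seed(55)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 500, TRUE,
                    prob = c(.24, .24, .24, .24, .04)), collapse = "")
  rng <- pwm_score_range(x, 0.8)
  hits <- scan_pwm(c(s = s), x, 0.8)
  orc <- oracle_pwm_scores(s, x)
  exp_fwd <- which(!is.na(orc$fwd) & orc$fwd >= rng[["threshold"]])
  exp_rev <- which(!is.na(orc$rev) & orc$rev >= rng[["threshold"]])
  expect_identical(hits$start[hits$strand == "+"], exp_fwd)
  expect_identical(hits$start[hits$strand == "-"], exp_rev)
  if (nrow(hits))
    expect_equal(
      hits$score[hits$strand == "+"], orc$fwd[exp_fwd], tolerance = 1e-6)
})

test_that("planted consensus scores maximally; threshold 1 is exact-only", {
  x <- toy_pwm()
  s <- paste0(plain_ac_seq(40), "ACGTAC", plain_ac_seq(40))
  hits <- scan_pwm(c(s = s), x, 0.8)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$start, 41L)
  expect_equal(plus$score, pwm_score_range(x)[["max"]], tolerance = 1e-9)

  # exact-threshold scan on a sequence without the optimum finds nothing
  s2 <- paste0(plain_ac_seq(40), "ACGTAA", plain_ac_seq(40))
  expect_identical(nrow(scan_pwm(c(s = s2), x, 1.0)), 0L)
  # shorter than the motif: empty result, no error
  expect_identical(nrow(scan_pwm(c(s = "ACG"), x)), 0L)
})

test_that("PWM hit counts are non-increasing in the threshold", {
  x <- toy_pwm()
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  n_prev <- Inf
  for (rt in c(0.3, 0.5, 0.7, 0.9)) {
    n <- nrow(scan_pwm(c(s = s), x, rt))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("module pairing is inclusive at the 40-bp gap, edge to edge", {
  # 0-based: E-box [10,16), cofactor [56,66) -> gap 40 -> module
  eb <- data.frame(peak_id = "p", start = 11L, end = 16L)
  co40 <- data.frame(peak_id = "p", start = 57L, end = 66L, motif = "m")
  expect_identical(nrow(find_modules(eb, co40)), 1L)
  expect_identical(find_modules(eb, co40)$gap, 40)
  co41 <- data.frame(peak_id = "p", start = 58L, end = 67L, motif = "m")
  expect_identical(nrow(find_modules(eb, co41)), 0L)
  # overlapping occurrences: gap 0
  co0 <- data.frame(peak_id = "p", start = 13L, end = 22L, motif = "m")
  expect_identical(find_modules(eb, co0)$gap, 0)
  # symmetric under swapping the hit lists' roles
  sw <- find_modules(co40[, c("peak_id", "start", "end")],
                     cbind(eb, motif = "e"), max_gap = 40)
  expect_identical(sw$gap, 40)
  # hits on different sequences never pair
  eb2 <- data.frame(peak_id = "q", start = 11L, end = 16L)
  expect_identical(nrow(find_modules(eb2, co40)), 0L)
})

test_that("module enrichment is seeded, reproducible and sided correctly", {
  x <- toy_pwm()
  set.seed(88)
  # 30 sequences, every one with a planted E-box + cofactor at gap 10 on
  # an A/C backbone (no background motifs)
  planted <- vapply(1:30, function(i)
    paste0(plain_ac_seq(60), "CAGGTG", plain_ac_seq(10), "ACGTAC",
           plain_ac_seq(60)), "")
  names(planted) <- sprintf("p%02d", 1:30)
  er <- module_enrichment(planted, x, n_shuffles = 30, seed = 4)
  expect_identical(er$observed, 30L)
  expect_gt(er$z, 2)
  er2 <- module_enrichment(planted, x, n_shuffles = 30, seed = 4)
  expect_identical(er, er2)

  # observed is independent of the number of shuffles
  er3 <- module_enrichment(planted, x, n_shuffles = 60, seed = 4)
  expect_identical(er3$observed, er$observed)
})

test_that("per-group E-box summaries count peaks and genes", {
  seqs <- c(a1 = paste0(plain_ac_seq(30), "CATGTG", plain_ac_seq(30)),
            a2 = plain_ac_seq(66),
            b1 = paste0("CACGTG", plain_ac_seq(60)))
  asg <- data.frame(cluster_id = c("c1", "c1", "c2"),
                    peak_id = c("a1", "a2", "b1"),
                    tissue = c("ECC", "Limb", "PNST"),
                    group = c("ECC-Limb", "ECC-Limb", "PNST-only"),
                    stringsAsFactors = FALSE)
  attr(asg, "tissues") <- c("ECC", "Limb", "PNST")
  es <- ebox_summary(asg, seqs)
  expect_equal(es$fraction[es$group == "ECC-Limb"], 0.5)
  expect_equal(es$fraction[es$group == "PNST-only"], 1.0)

  # empty groups are absent, not zero
  expect_false("ECC-only" %in% es$group)

  # peaks without sequences are excluded with a warning
  expect_warning(es2 <- ebox_summary(asg, seqs[-2]), "lack sequence")
  expect_equal(es2$n_peaks[es2$group == "ECC-Limb"], 1L)

  # gene rollup counts distinct associated genes of E-box-positive peaks
  assoc <- data.frame(peak_id = c("a1", "a1", "a2", "b1"),
                      gene = c("G1", "G2", "G3", "G4"),
                      signed_distance = 0, direction = "down",
                      within_50kb = TRUE, stringsAsFactors = FALSE)
  es3 <- ebox_summary(asg, seqs, assoc = assoc)
  expect_identical(es3$n_genes_with_ebox[es3$group == "ECC-Limb"], 2L)
})
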