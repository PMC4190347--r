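# Shared fixtures and independent oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# quick GRanges peak set (1-based closed coordinates)
make_peaks <- function(chrom, start, end, tissue = "T", ids = NULL,
                       summit = NA_integer_, chrom_sizes = NULL) {
  gr <- make_intervals(chrom, start, end, chrom_sizes = chrom_sizes)
  n <- length(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    peak_id = ids %||% sprintf("%s_pk%04d", tissue, seq_len(n)),
    tissue = tissue,
    summit = rep_len(as.integer(summit), n),
    tags = rep_len(10L, n), pvalue_score = rep_len(60, n),
    fold_enrichment = rep_len(5, n),
    down_gene = NA_character_, down_dist = NA_real_,
    up_gene = NA_character_, up_dist = NA_real_)
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fast, small synthetic study for tests that do not need the full design
small_config <- function(seed = 1, ...) {
  synth_config(
    n_chroms = 2, chrom_length = 250000, n_genes = 24,
    group_design = stats::setNames(c(3, 3, 3, 2, 2, 2, 1),
                                   overlap_group_levels(c("ECC", "Limb", "PNST"))),
    far_fraction = 0.25, seed = seed, ...)
}

# ---- independent oracles -------------------------------------------------

# O(n^2) all-pairs overlap-edge oracle over a combined peak data.frame
oracle_overlap_edges <- function(df, min_fraction = 0.05) {
  out <- list()
  for (i in seq_len(nrow(df) - 1L)) for (j in seq(i + 1L, nrow(df))) {
    if (df$tissue[i] == df$tissue[j] || df$chrom[i] != df$chrom[j]) next
    ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1L
    if (ov <= 0) next
    fa <- ov / (df$end[i] - df$start[i] + 1L)
    fb <- ov / (df$end[j] - df$start[j] + 1L)
    if (max(fa, fb) >= min_fraction)
      out[[length(out) + 1L]] <- sort(c(df$peak_id[i], df$peak_id[j]))
  }
  if (!length(out)) return(character())
  sort(vapply(out, paste, "", collapse = "|"))
}

# independent union-find for cluster counting
oracle_union_find <- function(ids, edge_a, edge_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edge_a)) {
    ra <- find(edge_a[k]); rb <- find(edge_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(ids, find, "")))
}

# regex oracle for IUPAC consensus scanning on both strands
oracle_scan_regex <- function(seq, pattern = "CANNTG") {
  iupac <- Biostrings::IUPAC_CODE_MAP
  to_re <- function(p) paste(vapply(strsplit(p, "")[[1]], function(ch) {
    letters <- strsplit(iupac[[ch]], "")[[1]]
    if (length(letters) == 1L) letters else
      paste0("[", paste(letters, collapse = ""), "]")
  }, ""), collapse = "")
  find_all <- function(s, re) {
    out <- integer(); from <- 1L
    repeat {
      m <- regexpr(re, substr(s, from, nchar(s)), perl = TRUE)
      if (m == -1L) break
      out <- c(out, from + as.integer(m) - 1L)
      from <- from + as.integer(m)
    }
    out
  }
  L <- nchar(pattern)
  fwd <- find_all(seq, to_re(pattern))
  rc_pat <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  rev <- find_all(seq, to_re(rc_pat))
  list(fwd = fwd, rev = rev, len = L)
}

# brute-force per-window PWM scores on both strands (N windows -> NA)
oracle_pwm_scores <- function(seq, x) {
  lo <- pwm_logodds(x)
  L <- ncol(lo)
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  if (n < L) return(list(fwd = numeric(), rev = numeric()))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_at <- function(w) {
    if (any(!w %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(L), function(j) lo[w[j], j], 0))
  }
  fwd <- vapply(seq_len(n - L + 1L), function(p)
    score_at(v[p:(p + L - 1L)]), 0)
  rev <- vapply(seq_len(n - L + 1L), function(p) {
    w <- rev(unname(comp[v[p:(p + L - 1L)]]))
    if (anyNA(w)) NA_real_ else score_at(w)
  }, 0)
  list(fwd = fwd, rev = rev)
}

# textbook pooled two-sample Student t
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(t), df = nx + ny - 2)
  list(t = t, p = p)
}

# random genome-free sequence scrubbed of a motif context, for enrichment
# fixtures: draws A/C-only backbones so no E-box or cofactor hit exists
plain_ac_seq <- function(n) {
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}
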