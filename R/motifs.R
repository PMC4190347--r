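empty_hits <- function() {
  data.frame(peak_id = character(), start = integer(), end = integer(),
             strand = character(), matched_seq = character(),
             motif = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

as_named_seqs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
  seqs
}

#' Extract peak sequences from a genome, after symmetric extension
#'
#' Peaks are conventionally extended +/- 200 bp before motif scanning;
#' the extension is clamped at chromosome ends.
#'
#' @param peaks `GRanges` with `peak_id`.
#' @param genome named `DNAStringSet`.
#' @param extend bp added on each side (default 200; use 0 for the raw
#'   peak sequence).
#' @return `DNAStringSet` named by `peak_id`.
#' @export
peak_sequences <- function(peaks, genome, extend = 200) {
  sizes <- setNames(Biostrings::width(genome), names(genome))
  ext <- extend_intervals(peaks, extend, chrom_sizes = sizes)
  chr <- as.character(GenomeInfoDb::seqnames(ext))
  out <- vapply(seq_along(ext), function(i)
    as.character(Biostrings::subseq(genome[[chr[i]]],
                                    GenomicRanges::start(ext)[i],
                                    GenomicRanges::end(ext)[i])), "")
  Biostrings::DNAStringSet(setNames(out, ext$peak_id))
}

#' Scan sequences for an IUPAC consensus motif on both strands
#'
#' An `N` in the scanned sequence matches only an `N` in the pattern.  For
#' a pattern that equals its own reverse complement (such as the E-box
#' `CANNTG`), antisense hits coincide positionally with sense hits and are
#' reported once with strand `"."`.
#'
#' @param seqs named character vector or `DNAStringSet` (names are treated
#'   as peak ids).
#' @param pattern IUPAC consensus string (default the E-box `CANNTG`).
#' @return `data.frame` of hits: `peak_id`, `start`, `end` (1-based closed
#'   offsets within each sequence), `strand`, `matched_seq`, `motif`,
#'   `score` (NA for consensus hits).
#' @export
scan_consensus <- function(seqs, pattern = "CANNTG") {
  letters_ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(letters_ok))
    stop_ps("invalid IUPAC letter in pattern: ",
            strsplit(pattern, "")[[1]][!letters_ok][1L])
  seqs <- as_named_seqs(seqs)
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(rc) == pattern
  rows <- lapply(names(seqs), function(id) {
    subj <- Biostrings::DNAString(seqs[[id]])
    one <- function(p, strand) {
      m <- Biostrings::matchPattern(p, subj, fixed = "subject")
      if (!length(m)) return(NULL)
      data.frame(peak_id = id, start = BiocGenerics::start(m),
                 end = BiocGenerics::end(m), strand = strand,
                 matched_seq = as.character(m), motif = pattern,
                 score = NA_real_, stringsAsFactors = FALSE)
    }
    if (palindromic) one(pat, ".")
    else rbind(one(pat, "+"), one(rc, "-"))
  })
  out <- do.call(rbind, c(rows, list(empty_hits())))
  rownames(out) <- NULL
  out[order(match(out$peak_id, names(seqs)), out$start), , drop = FALSE]
}

#' PWM score range and relative threshold
#' @param x a [pwm()].
#' @param rel_threshold fraction of the score range (0, 1].
#' @return Named vector `min`, `max`, `threshold` (log2-odds).
#' @export
pwm_score_range <- function(x, rel_threshold = 0.8) {
  stopifnot(rel_threshold > 0, rel_threshold <= 1)
  lo <- pwm_logodds(x)
  mn <- sum(apply(lo, 2, min)); mx <- sum(apply(lo, 2, max))
  c(min = mn, max = mx, threshold = mn + rel_threshold * (mx - mn))
}

#' Scan sequences with a position weight matrix on both strands
#'
#' Windows are scored by log2-odds against the PWM's background; a window
#' is a hit when its score reaches
#' `min_score + rel_threshold * (max_score - min_score)` (a matrix-
#' similarity-style range-relative threshold).  Windows containing `N` are
#' skipped.  Coordinates are always reported on the forward strand.
#'
#' @inheritParams scan_consensus
#' @param x a [pwm()].
#' @param rel_threshold fraction of the score range, in (0, 1] (default 0.8).
#' @return Hit `data.frame` as in [scan_consensus()], with `score` filled
#'   and `matched_seq` the strand-matched sequence.
#' @export
scan_pwm <- function(seqs, x, rel_threshold = 0.8) {
  stopifnot(inherits(x, "pwm"))
  seqs <- as_named_seqs(seqs)
  lo <- pwm_logodds(x)
  thr <- pwm_score_range(x, rel_threshold)[["threshold"]]
  L <- ncol(lo)
  rows <- lapply(names(seqs), function(id) {
    sq <- seqs[[id]]
    if (nchar(sq) < L) return(NULL)
    subj <- Biostrings::DNAString(sq)
    scan_one <- function(s, strand) {
      m <- suppressWarnings(
        Biostrings::matchPWM(lo, s, min.score = thr, with.score = TRUE))
      if (!length(m)) return(NULL)
      st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
      keep <- !grepl("N", as.character(m), fixed = TRUE)
      if (!any(keep)) return(NULL)
      st <- st[keep]; en <- en[keep]
      sc <- S4Vectors::mcols(m)$score[keep]
      ms <- as.character(m)[keep]
      if (strand == "-") {
        n <- length(s)
        tmp <- st; st <- n - en + 1L; en <- n - tmp + 1L
        o <- order(st); st <- st[o]; en <- en[o]; sc <- sc[o]; ms <- ms[o]
      }
      data.frame(peak_id = id, start = st, end = en, strand = strand,
                 matched_seq = ms, motif = x$name, score = as.numeric(sc),
                 stringsAsFactors = FALSE)
    }
    rbind(scan_one(subj, "+"),
          scan_one(Biostrings::reverseComplement(subj), "-"))
  })
  out <- do.call(rbind, c(rows, list(empty_hits())))
  rownames(out) <- NULL
  out[order(match(out$peak_id, names(seqs)), out$start, out$strand), ,
      drop = FALSE]
}

#' Pair E-box and cofactor hits into modules within a spacing window
#'
#' A module is an E-box occurrence and a cofactor occurrence on the same
#' scanned sequence whose closest edges are at most `max_gap` bp apart
#' (inclusive; overlapping occurrences have gap 0).  A centre-to-centre
#' variant is available.
#'
#' @param ebox_hits,cofactor_hits hit tables from [scan_consensus()] /
#'   [scan_pwm()], from the same sequences.
#' @param max_gap bp, inclusive (default 40).
#' @param gap_mode `"edge"` (default) or `"center"`.
#' @return `data.frame`: `peak_id`, `ebox_start`, `ebox_end`,
#'   `cofactor_start`, `cofactor_end`, `cofactor_motif`, `gap`.
#' @export
find_modules <- function(ebox_hits, cofactor_hits, max_gap = 40,
                         gap_mode = c("edge", "center")) {
  gap_mode <- match.arg(gap_mode)
  out <- merge(
    setNames(ebox_hits[, c("peak_id", "start", "end")],
             c("peak_id", "ebox_start", "ebox_end")),
    setNames(cofactor_hits[, c("peak_id", "start", "end", "motif")],
             c("peak_id", "cofactor_start", "cofactor_end", "cofactor_motif")),
    by = "peak_id")
  if (!nrow(out)) {
    out$gap <- numeric()
    return(out)
  }
  out$gap <- if (gap_mode == "edge")
    pmax(0, pmax(out$cofactor_start - out$ebox_end - 1L,
                 out$ebox_start - out$cofactor_end - 1L))
  else
    abs((out$ebox_start + out$ebox_end) / 2 -
          (out$cofactor_start + out$cofactor_end) / 2)
  out <- out[out$gap <= max_gap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

#' Shuffle-based enrichment z-score for E-box/cofactor modules
#'
#' The observed statistic is the number of sequences carrying at least one
#' module; the background distribution comes from rescanning per-sequence
#' mononucleotide shuffles (length and base composition preserved).  A
#' |z| >= 2 is the conventional reporting threshold; both tails are
#' meaningful (over- and under-representation).
#'
#' @inheritParams scan_consensus
#' @inheritParams find_modules
#' @param x cofactor [pwm()].
#' @param ebox_pattern IUPAC consensus (default `CANNTG`).
#' @param rel_threshold PWM threshold as in [scan_pwm()].
#' @param n_shuffles number of shuffled backgrounds (>= 10; default 100).
#' @param seed RNG seed; results are bit-reproducible given (inputs, seed).
#' @return List of class `enrichment_result`: `name`, `observed`,
#'   `expected_mean`, `expected_sd`, `z`, `n_shuffles`, `seed`.
#' @export
module_enrichment <- function(seqs, x, ebox_pattern = "CANNTG",
                              max_gap = 40, rel_threshold = 0.8,
                              n_shuffles = 100, seed = NULL) {
  stopifnot(n_shuffles >= 10)
  seqs <- as_named_seqs(seqs)
  count_modules <- function(ss) {
    mods <- find_modules(scan_consensus(ss, ebox_pattern),
                         scan_pwm(ss, x, rel_threshold), max_gap = max_gap)
    length(unique(mods$peak_id))
  }
  observed <- count_modules(seqs)
  bg <- with_seed(seed, vapply(seq_len(n_shuffles), function(k) {
    count_modules(setNames(vapply(seqs, shuffle_seq, ""), names(seqs)))
  }, 0))
  em <- mean(bg); es <- sd(bg)
  if (is.na(es) || es == 0) {
    warn_ps("zero background variance; z reported as a +/-Inf sentinel")
    z <- if (observed == em) 0 else sign(observed - em) * Inf
  } else z <- (observed - em) / es
  structure(list(name = paste0(ebox_pattern, "+", x$name),
                 observed = observed, expected_mean = em, expected_sd = es,
                 z = z, n_shuffles = n_shuffles, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("module enrichment '%s': observed %d, background %.2f +/- %.2f, z = %.2f (%d shuffles)\n",
              x$name, x$observed, x$expected_mean, x$expected_sd, x$z,
              x$n_shuffles))
  invisible(x)
}

#' E-box content per tissue-sharing group
#'
#' Counts, per overlap group, the peaks whose (extended) sequence carries
#' at least one E-box consensus, plus an optional gene-level rollup
#' (distinct associated genes having at least one E-box-positive peak).
#'
#' @param assignments from [classify_overlap_groups()].
#' @param seqs sequences named by `peak_id` (see [peak_sequences()]).
#' @param pattern IUPAC consensus (default `CANNTG`).
#' @param assoc optional associations from [assign_nearest_genes()] for
#'   the gene rollup (rows with `within_50kb` are used).
#' @return `data.frame` per non-empty group: `group`, `n_peaks`,
#'   `n_with_ebox`, `fraction`, and `n_genes_with_ebox` when `assoc` is
#'   given.  Peaks without a sequence are excluded;
#'   `attr(, "missing_sequence")` lists them.
#' @export
ebox_summary <- function(assignments, seqs, pattern = "CANNTG",
                         assoc = NULL) {
  seqs <- as_named_seqs(seqs)
  missing <- setdiff(assignments$peak_id, names(seqs))
  if (length(missing))
    warn_ps(length(missing), " peak(s) lack sequence and are excluded")
  a <- assignments[assignments$peak_id %in% names(seqs), , drop = FALSE]
  hits <- scan_consensus(seqs[a$peak_id], pattern)
  has_ebox <- a$peak_id %in% hits$peak_id
  out <- do.call(rbind, lapply(split(seq_len(nrow(a)), a$group), function(i) {
    data.frame(group = a$group[i[1L]], n_peaks = length(i),
               n_with_ebox = sum(has_ebox[i]),
               fraction = sum(has_ebox[i]) / length(i),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(assoc)) {
    pos_peaks <- a$peak_id[has_ebox]
    aa <- assoc[assoc$within_50kb & assoc$peak_id %in% pos_peaks, ,
                drop = FALSE]
    aa$group <- a$group[match(aa$peak_id, a$peak_id)]
    ng <- vapply(split(toupper(aa$gene), aa$group),
                 function(g) length(unique(g)), 0L)
    out$n_genes_with_ebox <- as.integer(ng[out$group])
    out$n_genes_with_ebox[is.na(out$n_genes_with_ebox)] <- 0L
  }
  rownames(out) <- NULL
  attr(out, "missing_sequence") <- missing
  out
}
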