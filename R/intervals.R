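#' Genomic interval conventions
#'
#' Peaks, genes and motif hits are carried as [GenomicRanges::GRanges]
#' (1-based, closed intervals), the standard Bioconductor container.
#' External formats are converted at the I/O boundary: BED-style 0-based
#' half-open coordinates gain 1 on the start, MACS-style 1-based inclusive
#' tables are taken verbatim.  `length == end - start + 1` internally.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end interval bounds in the convention named by `coords`.
#' @param coords `"1-based"` (closed, as in MACS tables) or `"0-based"`
#'   (half-open, as in BED).
#' @param strand strand per interval: `"+"`, `"-"` or `"."` (unstranded;
#'   stored as `"*"`).
#' @param chrom_sizes optional named vector of chromosome lengths (bp) used
#'   to attach `seqlengths`.
#' @return A `GRanges` object.
#' @examples
#' make_intervals("chr1", 100, 199, coords = "0-based")  # the BED row 100-199
#' @export
make_intervals <- function(chrom, start, end, coords = c("1-based", "0-based"),
                           strand = ".", chrom_sizes = NULL) {
  coords <- match.arg(coords)
  if (any(!nzchar(chrom))) stop_ps("chromosome names must be non-empty")
  if (coords == "0-based") start <- start + 1L
  if (any(end < start)) stop_ps("intervals must satisfy start <= end (non-empty)")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  if (!is.null(chrom_sizes)) {
    if (any(chrom_sizes <= 0)) stop_ps("chromosome sizes must be positive")
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  }
  gr
}

#' Pairwise overlap length of two interval vectors
#'
#' Element-wise shared nucleotides of `a[i]` and `b[i]` (recycled), zero for
#' intervals on different chromosomes or disjoint intervals.
#'
#' @param a,b `GRanges` vectors of equal (or recyclable) length.
#' @return Integer vector of overlapping base pairs.
#' @export
overlap_length <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  as.integer(pmax(0L, ifelse(same, ov, 0L)))
}

#' Fractional overlap of two interval vectors
#'
#' The sharing criterion for peaks is a minimum fractional overlap (default
#' 5% elsewhere in the package); this returns both fractions so either or
#' both sides can be thresholded.
#'
#' @inheritParams overlap_length
#' @return `data.frame` with columns `overlap_bp`, `frac_a`, `frac_b`
#'   (each fraction = shared bp / own width, in `[0, 1]`).
#' @export
fractional_overlap <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  ov <- overlap_length(a, b)
  data.frame(
    overlap_bp = ov,
    frac_a = ov / GenomicRanges::width(a),
    frac_b = ov / GenomicRanges::width(b)
  )
}

#' Extend intervals symmetrically, clamped to chromosome bounds
#'
#' Peak sequences are conventionally extended +/- 200 bp before motif
#' scanning; the extension never runs past position 1 or the chromosome end.
#'
#' @param x `GRanges`.
#' @param pad non-negative bp added on each side.
#' @param chrom_sizes named vector of chromosome lengths; defaults to
#'   `seqlengths(x)`.  Every chromosome of `x` must have a known length.
#' @return `GRanges` of the same length with widened ranges.
#' @export
extend_intervals <- function(x, pad, chrom_sizes = NULL) {
  stopifnot(pad >= 0)
  if (is.null(chrom_sizes)) chrom_sizes <- GenomeInfoDb::seqlengths(x)
  chr <- as.character(GenomeInfoDb::seqnames(x))
  missing_chr <- setdiff(unique(chr), names(chrom_sizes)[!is.na(chrom_sizes)])
  if (length(missing_chr))
    stop_ps("no chromosome length known for: ", paste(missing_chr, collapse = ", "))
  len <- unname(chrom_sizes[chr])
  GenomicRanges::ranges(x) <- IRanges::IRanges(
    pmax(1L, GenomicRanges::start(x) - as.integer(pad)),
    pmin(as.integer(len), GenomicRanges::end(x) + as.integer(pad))
  )
  x
}
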