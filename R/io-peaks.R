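#' MACS-style peak table dialect
#'
#' Column mapping and conventions for tab- or comma-separated peak tables as
#' produced by MACS (xls export converted to text).  The p-value column may
#' hold either MACS's `-10*log10(p)` score or a raw p-value; this is never
#' auto-guessed and must be declared.
#'
#' @param sep field separator (`"\t"` or `","`).
#' @param pvalue `"neglog10"` (MACS convention) or `"raw"`.
#' @param coords coordinate convention of the start/end columns.
#' @param columns named list mapping internal field names to file column
#'   names.  Internal names: `chrom`, `start`, `end`, `length`, `summit`,
#'   `tags`, `pvalue`, `fold_enrichment`, `down_dist`, `down_gene`,
#'   `up_dist`, `up_gene`, `peak_id`.  Only `chrom`, `start`, `end` are
#'   mandatory in the file.
#' @return A list of class `macs_dialect`.
#' @export
macs_dialect <- function(sep = "\t", pvalue = c("neglog10", "raw"),
                         coords = c("1-based", "0-based"),
                         columns = list()) {
  defaults <- list(
    chrom = "chr", start = "start", end = "end", length = "length",
    summit = "summit", tags = "tags", pvalue = "pvalue",
    fold_enrichment = "fold_enrichment",
    down_dist = "down_dist", down_gene = "down_gene",
    up_dist = "up_dist", up_gene = "up_gene", peak_id = "peak_id"
  )
  defaults[names(columns)] <- columns
  structure(list(sep = sep, pvalue = match.arg(pvalue),
                 coords = match.arg(coords), columns = defaults),
            class = "macs_dialect")
}

macs_optional_numeric <- c("length", "summit", "tags", "pvalue",
                           "fold_enrichment", "down_dist", "up_dist")

#' Read a MACS-style peak table
#'
#' Every data row becomes one peak; coordinates are converted to the
#' internal 1-based closed convention; nearest-gene annotation columns
#' (signed distances and names of the nearest downstream and upstream
#' genes, as carried in MACS post-processing tables) are stored verbatim.
#'
#' @param path file path.
#' @param tissue tissue/sample label attached to every peak.
#' @param dialect a [macs_dialect()].
#' @return `GRanges` with metadata columns `peak_id`, `tissue`, `summit`
#'   (offset from peak start, 0-based), `tags`, `pvalue_score` (always
#'   `-10*log10(p)` internally), `fold_enrichment`, `down_gene`,
#'   `down_dist`, `up_gene`, `up_dist`.
#' @export
read_macs_peaks <- function(path, tissue, dialect = macs_dialect()) {
  if (!file.exists(path)) stop_ps("no such file: ", path)
  df <- read.delim(path, sep = dialect$sep, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  cols <- dialect$columns
  mandatory <- c("chrom", "start", "end")
  absent <- mandatory[!unlist(cols[mandatory]) %in% names(df)]
  if (length(absent))
    stop_ps("peak table ", path, " lacks mandatory column(s): ",
            paste(unlist(cols[absent]), collapse = ", "))
  if (nrow(df) == 0L) {
    warn_ps("peak table ", path, " has no data rows; returning empty set")
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      peak_id = character(), tissue = character(), summit = integer(),
      tags = integer(), pvalue_score = numeric(), fold_enrichment = numeric(),
      down_gene = character(), down_dist = numeric(),
      up_gene = character(), up_dist = numeric())
    return(gr)
  }
  num_field <- function(field) {
    nm <- cols[[field]]
    if (!nm %in% names(df)) return(rep(NA_real_, nrow(df)))
    raw <- df[[nm]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out) & !is.na(raw) & nzchar(trimws(as.character(raw))))
    if (length(bad))
      stop_ps("unparsable numeric in column '", nm, "' of ", path,
              " at data row ", bad[1L], ": '", raw[bad[1L]], "'")
    out
  }
  chr_field <- function(field) {
    nm <- cols[[field]]
    if (!nm %in% names(df)) rep(NA_character_, nrow(df)) else as.character(df[[nm]])
  }
  start <- num_field("start"); end <- num_field("end")
  if (anyNA(start) || anyNA(end)) stop_ps("missing start/end value in ", path)
  gr <- make_intervals(chr_field("chrom"), start, end, coords = dialect$coords)
  pv <- num_field("pvalue")
  if (dialect$pvalue == "raw") pv <- -10 * log10(pv)
  ids <- chr_field("peak_id")
  if (all(is.na(ids)))
    ids <- sprintf("%s_peak_%05d", tissue, seq_len(nrow(df)))
  if (anyDuplicated(ids)) stop_ps("duplicate peak_id values in ", path)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    peak_id = ids, tissue = tissue,
    summit = as.integer(num_field("summit")),
    tags = as.integer(num_field("tags")),
    pvalue_score = pv,
    fold_enrichment = num_field("fold_enrichment"),
    down_gene = chr_field("down_gene"), down_dist = num_field("down_dist"),
    up_gene = chr_field("up_gene"), up_dist = num_field("up_dist"))
  len <- num_field("length")
  ok <- is.na(len) | len == GenomicRanges::width(gr)
  if (!all(ok))
    stop_ps("length column disagrees with end - start + 1 at data row ",
            which(!ok)[1L], " of ", path)
  fe <- gr$fold_enrichment
  if (any(!is.na(fe) & fe <= 0)) stop_ps("fold_enrichment must be > 0 in ", path)
  sm <- gr$summit
  bad <- !is.na(sm) & (sm < 0L | sm >= GenomicRanges::width(gr))
  if (any(bad)) stop_ps("summit offset outside peak at data row ", which(bad)[1L])
  gr
}

#' Write a peak set as BED6 plus a sidecar annotation TSV
#'
#' The BED file carries coordinates (0-based half-open), `peak_id` as the
#' name, `tags` as the score and strand; all remaining metadata columns go
#' to `<path>.annot.tsv` keyed by `peak_id`, so that
#' [read_peaks_bed()] round-trips losslessly.
#'
#' @param peaks `GRanges` as returned by [read_macs_peaks()].
#' @param path output BED path; the sidecar is written next to it.
#' @return Invisibly, the two paths written.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- peaks$tags
  score[is.na(score)] <- 0L
  bed <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = peaks$peak_id,
    score = score,
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(peaks))))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  annot_path <- paste0(path, ".annot.tsv")
  annot <- as.data.frame(S4Vectors::mcols(peaks))
  write.table(annot, annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = path, annot = annot_path))
}

#' Write a peak set as a MACS-style table
#'
#' Emits the default tab-separated dialect read back by
#' [read_macs_peaks()]: 1-based inclusive coordinates, `-10*log10(p)`
#' p-value score, nearest-gene annotation columns.
#'
#' @param peaks annotated `GRanges`.
#' @param path output path.
#' @export
write_macs_peaks <- function(peaks, path) {
  df <- data.frame(
    chr = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks),
    end = GenomicRanges::end(peaks),
    length = GenomicRanges::width(peaks),
    summit = peaks$summit,
    tags = peaks$tags,
    pvalue = peaks$pvalue_score,
    fold_enrichment = peaks$fold_enrichment,
    down_dist = peaks$down_dist,
    down_gene = peaks$down_gene,
    up_dist = peaks$up_dist,
    up_gene = peaks$up_gene,
    peak_id = peaks$peak_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak set written by [write_peaks_bed()]
#'
#' @param path BED path (sidecar `<path>.annot.tsv` expected next to it).
#' @param chrom_sizes optional named chromosome lengths to attach.
#' @return `GRanges` equivalent to the one written.
#' @export
read_peaks_bed <- function(path, chrom_sizes = NULL) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  gr <- make_intervals(bed$chrom, bed$start, bed$end, coords = "0-based",
                       strand = bed$strand, chrom_sizes = chrom_sizes)
  annot <- read.delim(paste0(path, ".annot.tsv"), stringsAsFactors = FALSE)
  annot <- annot[match(bed$name, annot$peak_id), , drop = FALSE]
  for (col in c("pvalue_score", "fold_enrichment", "down_dist", "up_dist"))
    if (col %in% names(annot)) annot[[col]] <- as.numeric(annot[[col]])
  for (col in c("summit", "tags"))
    if (col %in% names(annot)) annot[[col]] <- as.integer(annot[[col]])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(annot, row.names = NULL)
  gr
}
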