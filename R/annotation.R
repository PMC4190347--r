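#' Location category levels, in precedence order
#' @export
location_levels <- c("promoter", "5'UTR", "3'UTR", "coding-exon",
                     "intron", "intergenic")

peak_edge_distance <- function(tss, start, end) {
  ifelse(tss >= start & tss <= end, 0,
         ifelse(tss > end, tss - end, -(start - tss)))
}

#' Associate peaks with their nearest genes by TSS distance
#'
#' For every peak the nearest TSS in each genomic direction (downstream =
#' increasing coordinate, upstream = decreasing) is recorded with a signed
#' distance measured from the nearest peak edge; a TSS inside the peak has
#' distance 0 and counts as nearest in both directions.
#'
#' @param peaks `GRanges` with `peak_id` metadata.
#' @param genes `gene_models` table.
#' @param threshold bp threshold used to set the `within_50kb` flag
#'   (inclusive; default 50000).
#' @return `data.frame` with columns `peak_id`, `gene`, `signed_distance`,
#'   `direction` (`"down"`/`"up"`), `within_50kb`.  Peaks on chromosomes
#'   without genes contribute no rows (a warning names those chromosomes).
#' @export
assign_nearest_genes <- function(peaks, genes, threshold = 50000) {
  pk_chr <- as.character(GenomeInfoDb::seqnames(peaks))
  empty_chr <- setdiff(unique(pk_chr), unique(genes$chrom))
  if (length(empty_chr))
    warn_ps("no genes on chromosome(s): ", paste(empty_chr, collapse = ", "),
            "; affected peaks get no association")
  rows <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    g <- genes[genes$chrom == pk_chr[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- peak_edge_distance(g$tss, GenomicRanges::start(peaks)[i],
                            GenomicRanges::end(peaks)[i])
    pick <- function(idx, direction) {
      if (!length(idx)) return(NULL)
      best <- idx[order(abs(d[idx]), g$tss[idx], g$gene[idx])][1L]
      data.frame(peak_id = peaks$peak_id[i], gene = g$gene[best],
                 signed_distance = d[best], direction = direction,
                 stringsAsFactors = FALSE)
    }
    rows[[i]] <- rbind(pick(which(d >= 0), "down"), pick(which(d <= 0), "up"))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak_id = character(), gene = character(),
                      signed_distance = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  out$within_50kb <- abs(out$signed_distance) <= threshold
  rownames(out) <- NULL
  out
}

#' Fill a peak set's nearest-gene metadata columns from an annotation
#'
#' Writes `down_gene`, `down_dist`, `up_gene`, `up_dist` into the peaks'
#' metadata, the same fields a MACS post-processing table carries.
#'
#' @inheritParams assign_nearest_genes
#' @return The peaks with updated metadata columns.
#' @export
annotate_peaks <- function(peaks, genes) {
  assoc <- assign_nearest_genes(peaks, genes)
  for (dir in c("down", "up")) {
    a <- assoc[assoc$direction == dir, , drop = FALSE]
    idx <- match(peaks$peak_id, a$peak_id)
    S4Vectors::mcols(peaks)[[paste0(dir, "_gene")]] <- a$gene[idx]
    S4Vectors::mcols(peaks)[[paste0(dir, "_dist")]] <- a$signed_distance[idx]
  }
  peaks
}

#' Filter peaks by distance to the nearest TSS
#'
#' Keeps peaks whose nearest TSS (the smaller of the absolute downstream
#' and upstream distances) lies within `threshold` bp, boundary inclusive.
#' Distances are taken either from the peaks' annotation columns as read
#' from the table (`distances = "table"`) or recomputed from a gene model
#' (`distances = "computed"`).  Peaks with no recorded distance in either
#' direction are excluded and counted in the attached report.
#'
#' @param peaks annotated `GRanges` (see [annotate_peaks()] /
#'   [read_macs_peaks()]).
#' @param threshold bp, inclusive (default 50000).
#' @param distances `"table"` or `"computed"`.
#' @param genes `gene_models`, required for `distances = "computed"`.
#' @return Filtered `GRanges`; `attr(, "tss_filter_report")` holds counts
#'   of input, kept, dropped-by-distance and dropped-for-missing peaks.
#' @export
filter_tss_distance <- function(peaks, threshold = 50000,
                                distances = c("table", "computed"),
                                genes = NULL) {
  distances <- match.arg(distances)
  if (distances == "computed") {
    if (is.null(genes)) stop_ps("distances = 'computed' requires `genes`")
    peaks <- annotate_peaks(peaks, genes)
  }
  dmin <- pmin(abs(peaks$down_dist), abs(peaks$up_dist), na.rm = TRUE)
  dmin[is.na(peaks$down_dist) & is.na(peaks$up_dist)] <- NA_real_
  keep <- !is.na(dmin) & dmin <= threshold
  out <- peaks[keep]
  attr(out, "tss_filter_report") <- c(
    input = length(peaks), kept = sum(keep),
    dropped_distance = sum(!keep & !is.na(dmin)),
    dropped_no_association = sum(is.na(dmin)))
  out
}

#' Filter peaks by expression of their associated genes
#'
#' A peak survives if at least one of its (up to two) nearest genes within
#' the TSS window is in the tissue's expressed-gene set; gene symbols are
#' compared case-insensitively.
#'
#' @param peaks `GRanges`.
#' @param assoc associations from [assign_nearest_genes()]; only rows with
#'   `within_50kb` are consulted.
#' @param expr an `expression_set`.
#' @return List with `peaks` (surviving `GRanges`) and `genes` (sorted,
#'   deduplicated expressed genes associated with surviving peaks).
#' @export
filter_by_expression <- function(peaks, assoc, expr) {
  if (!length(expr$genes)) {
    warn_ps("empty expression set; no peaks survive")
    return(list(peaks = peaks[0], genes = character()))
  }
  a <- assoc[assoc$within_50kb & toupper(assoc$gene) %in% expr$genes, ,
             drop = FALSE]
  a <- a[a$peak_id %in% peaks$peak_id, , drop = FALSE]
  keep <- peaks$peak_id %in% a$peak_id
  list(peaks = peaks[keep], genes = sort(unique(toupper(a$gene))))
}

classify_summit <- function(chrom, pos, genes, promoter_up, promoter_down) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  best <- length(location_levels)  # intergenic
  for (i in seq_len(nrow(g))) {
    tss <- g$tss[i]
    prom <- if (g$strand[i] == "+")
      pos >= tss - promoter_up && pos <= tss + promoter_down - 1L
    else
      pos <= tss + promoter_up && pos >= tss - promoter_down + 1L
    cat_i <- NA_integer_
    if (prom) cat_i <- 1L
    else if (pos >= g$tx_start[i] && pos <= g$tx_end[i]) {
      in_exon <- any(pos >= g$exon_starts[[i]] & pos <= g$exon_ends[[i]])
      if (!in_exon) cat_i <- 5L  # intron
      else if (is.na(g$cds_start[i]) || is.na(g$cds_end[i])) cat_i <- 4L
      else if (pos < g$cds_start[i]) cat_i <- if (g$strand[i] == "+") 2L else 3L
      else if (pos > g$cds_end[i]) cat_i <- if (g$strand[i] == "+") 3L else 2L
      else cat_i <- 4L  # coding exon
    }
    if (!is.na(cat_i) && cat_i < best) best <- cat_i
  }
  best
}

#' Classify peak summits by genomic location
#'
#' Each peak's summit position (peak start + summit offset; midpoint when
#' no summit is recorded) is assigned exactly one category with precedence
#' promoter > 5'UTR > 3'UTR > coding-exon > intron > intergenic, taken over
#' all genes.  The promoter window is strand-aware:
#' `[TSS - promoter_up, TSS + promoter_down)` in transcription direction.
#'
#' @param peaks `GRanges`.
#' @param genes `gene_models`.
#' @param promoter_up,promoter_down promoter window, bp (defaults 1000/100).
#' @return Factor of length `length(peaks)` with levels [location_levels].
#' @export
classify_locations <- function(peaks, genes, promoter_up = 1000,
                               promoter_down = 100) {
  if (!length(peaks))
    return(factor(character(), levels = location_levels))
  summit <- peaks$summit
  if (is.null(summit)) summit <- rep(NA_integer_, length(peaks))
  pos <- ifelse(is.na(summit),
                as.integer((GenomicRanges::start(peaks) +
                              GenomicRanges::end(peaks)) %/% 2),
                GenomicRanges::start(peaks) + as.integer(summit))
  chr <- as.character(GenomeInfoDb::seqnames(peaks))
  idx <- vapply(seq_along(peaks), function(i)
    classify_summit(chr[i], pos[i], genes, promoter_up, promoter_down), 0L)
  factor(location_levels[idx], levels = location_levels)
}

#' Genomic-location distribution of a peak set
#'
#' @inheritParams classify_locations
#' @return `data.frame` with `category`, `count`, `percentage` (percentages
#'   sum to 100 for non-empty sets; all zero for an empty set).
#' @export
location_distribution <- function(peaks, genes, promoter_up = 1000,
                                  promoter_down = 100) {
  calls <- classify_locations(peaks, genes, promoter_up, promoter_down)
  counts <- as.integer(table(calls))
  data.frame(category = location_levels, count = counts,
             percentage = if (sum(counts)) 100 * counts / sum(counts)
                          else rep(0, length(counts)),
             stringsAsFactors = FALSE)
}
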