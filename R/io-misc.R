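#' Read a gene-model table
#'
#' Eight mandatory tab-separated columns: `gene`, `chrom`, `strand` (+/-),
#' `tss`, `tx_start`, `tx_end`, `exon_starts`, `exon_ends` (comma-separated
#' lists), plus optional `cds_start`, `cds_end` for UTR calls.  Coordinates
#' are 1-based closed.  The TSS must equal `tx_start` on + genes and
#' `tx_end` on - genes; exons must be sorted, non-overlapping and inside
#' the transcript.
#'
#' @param path file path.
#' @return `data.frame` of class `gene_models` with integer list-columns
#'   `exon_starts`, `exon_ends`.
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_ps("gene-model table lacks column(s): ", paste(absent, collapse = ", "))
  df$exon_starts <- lapply(strsplit(as.character(df$exon_starts), ","), as.integer)
  df$exon_ends <- lapply(strsplit(as.character(df$exon_ends), ","), as.integer)
  if (!"cds_start" %in% names(df)) df$cds_start <- NA_integer_
  if (!"cds_end" %in% names(df)) df$cds_end <- NA_integer_
  validate_gene_models(df)
}

#' Assemble a gene-model table from vectors
#'
#' @param gene,chrom,strand,tss,tx_start,tx_end per-gene vectors.
#' @param exon_starts,exon_ends lists of integer vectors (one per gene).
#' @param cds_start,cds_end optional CDS bounds (NA = non-coding model).
#' @return `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene, chrom, strand, tss, tx_start, tx_end,
                        exon_starts, exon_ends,
                        cds_start = NA_integer_, cds_end = NA_integer_) {
  df <- data.frame(gene = gene, chrom = chrom, strand = strand,
                   tss = as.integer(tss), tx_start = as.integer(tx_start),
                   tx_end = as.integer(tx_end), stringsAsFactors = FALSE)
  df$exon_starts <- lapply(exon_starts, as.integer)
  df$exon_ends <- lapply(exon_ends, as.integer)
  df$cds_start <- rep_len(as.integer(cds_start), nrow(df))
  df$cds_end <- rep_len(as.integer(cds_end), nrow(df))
  validate_gene_models(df)
}

validate_gene_models <- function(df) {
  if (!all(df$strand %in% c("+", "-")))
    stop_ps("gene strand must be '+' or '-'")
  exp_tss <- ifelse(df$strand == "+", df$tx_start, df$tx_end)
  bad <- which(df$tss != exp_tss)
  if (length(bad))
    stop_ps("gene '", df$gene[bad[1L]],
            "': tss must equal tx_start (+) or tx_end (-)")
  for (i in seq_len(nrow(df))) {
    s <- df$exon_starts[[i]]; e <- df$exon_ends[[i]]
    if (length(s) != length(e) || any(e < s))
      stop_ps("gene '", df$gene[i], "': malformed exons")
    if (is.unsorted(s, strictly = TRUE) ||
        (length(s) > 1L && any(s[-1L] <= e[-length(e)])))
      stop_ps("gene '", df$gene[i], "': exons must be sorted, non-overlapping")
    if (s[1L] < df$tx_start[i] || e[length(e)] > df$tx_end[i])
      stop_ps("gene '", df$gene[i], "': exons outside transcript")
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write a gene-model table readable by [read_gene_models()]
#' @param genes `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  out <- as.data.frame(genes[, c("gene", "chrom", "strand", "tss",
                                 "tx_start", "tx_end")])
  out$exon_starts <- vapply(genes$exon_starts, paste, "", collapse = ",")
  out$exon_ends <- vapply(genes$exon_ends, paste, "", collapse = ",")
  out$cds_start <- genes$cds_start
  out$cds_end <- genes$cds_end
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expressed-gene list
#'
#' Accepts either one gene symbol per line (no header) or a two-column
#' `gene,flag` table (header required; rows with flag 1/TRUE/yes are
#' expressed).  Symbols are uppercased and deduplicated; matching elsewhere
#' in the package is case-insensitive exact (no alias resolution).
#'
#' @param path file path.
#' @param tissue tissue label.
#' @return List of class `expression_set` with elements `tissue`, `genes`.
#' @export
read_expression_list <- function(path, tissue) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    stop_ps("expression list ", path, " is empty")
  if (grepl("[,\t]", first)) {
    sep <- if (grepl(",", first)) "," else "\t"
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop_ps("flag-table expression list needs 2 columns")
    flag <- tolower(trimws(as.character(df[[2L]])))
    genes <- df[[1L]][flag %in% c("1", "true", "yes", "expressed")]
  } else {
    genes <- readLines(path)
  }
  genes <- unique(toupper(trimws(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop_ps("expression list ", path, " has no genes")
  expression_set(tissue, genes)
}

#' @rdname read_expression_list
#' @param genes character vector of symbols (normalised on construction).
#' @export
expression_set <- function(tissue, genes) {
  structure(list(tissue = tissue, genes = unique(toupper(trimws(genes)))),
            class = "expression_set")
}

#' Read a ChIP-qPCR Ct table
#'
#' CSV with named columns `region_id`, `antibody` (the IgG control rows are
#' identified case-insensitively as `"IgG"`), `replicate`, `ct` and, unless
#' the `"no-input"` dialect is chosen, `input_ct`.
#'
#' @param path file path.
#' @param dialect `"standard"` (input-normalised) or `"no-input"` (the
#'   `input_ct` column is absent and treated as 0 for every row).
#' @return `data.frame` of class `qpcr_table`.
#' @export
read_qpcr_table <- function(path, dialect = c("standard", "no-input")) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  need <- c("region_id", "antibody", "replicate", "ct")
  if (dialect == "standard") need <- c(need, "input_ct")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_ps("qPCR table lacks column(s): ", paste(absent, collapse = ", "))
  if (dialect == "no-input") df$input_ct <- 0
  qpcr_table(df$region_id, df$antibody, df$replicate, df$ct, df$input_ct)
}

#' @rdname read_qpcr_table
#' @param region_id,antibody,replicate,ct,input_ct column vectors.
#' @export
qpcr_table <- function(region_id, antibody, replicate, ct, input_ct = 0) {
  df <- data.frame(region_id = as.character(region_id),
                   antibody = as.character(antibody),
                   replicate = as.integer(replicate),
                   ct = as.numeric(ct),
                   input_ct = rep_len(as.numeric(input_ct), length(ct)),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$ct)) || any(!is.finite(df$input_ct)))
    stop_ps("Ct values must be finite")
  if (any(df$ct <= 0 | df$ct >= 50))
    stop_ps("Ct outside (0, 50): row ", which(df$ct <= 0 | df$ct >= 50)[1L])
  key <- paste(df$region_id, df$antibody, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop_ps("duplicate (region, antibody, replicate): ",
            gsub("\r", "/", key[duplicated(key)][1L]))
  for (r in unique(df$region_id)) {
    ab <- unique(is_igg(df$antibody[df$region_id == r]))
    if (length(ab) < 2L)
      warn_ps("region '", r, "' has only one antibody class")
  }
  class(df) <- c("qpcr_table", "data.frame")
  df
}

is_igg <- function(antibody) tolower(antibody) == "igg"

#' Read a genome FASTA
#'
#' Standard multi-record, line-wrapped FASTA; sequences are uppercased and
#' any letter outside `A,C,G,T,N` (IUPAC ambiguity codes, gaps) is mapped
#' to `N` with a warning.
#'
#' @param path file path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  s <- toupper(as.character(raw))
  n_other <- sum(nchar(gsub("[ACGTN]", "", s)))
  if (n_other > 0) {
    warn_ps(n_other, " non-ACGTN letter(s) mapped to N")
    s <- gsub("[^ACGTN]", "N", s)
  }
  names(s) <- vapply(strsplit(names(raw), "\\s+"), `[`, "", 1L)
  Biostrings::DNAStringSet(s)
}

#' Write a genome FASTA
#' @param genome `DNAStringSet`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
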