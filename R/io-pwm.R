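#' Construct a position weight matrix object
#'
#' Holds raw per-position nucleotide counts together with the background
#' model and pseudocount used to turn them into log-odds scores.
#'
#' @param name motif name.
#' @param counts 4 x L non-negative matrix with rownames `A,C,G,T`.
#' @param background length-4 base frequencies (A,C,G,T) summing to 1.
#' @param pseudocount small positive count added to every cell before
#'   normalisation.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, counts, background = rep(0.25, 4), pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(counts) < 4L) stop_ps("motif '", name, "': length must be >= 4")
  if (any(counts < 0)) stop_ps("motif '", name, "': negative counts")
  if (any(colSums(counts) <= 0)) stop_ps("motif '", name, "': empty column")
  if (abs(sum(background) - 1) > 1e-9)
    stop_ps("motif '", name, "': background must sum to 1")
  stopifnot(pseudocount > 0)
  structure(list(name = name, counts = counts,
                 background = setNames(background, c("A", "C", "G", "T")),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%d bp), consensus %s\n",
              x$name, ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' Log2-odds score matrix of a PWM
#'
#' Counts plus pseudocount are column-normalised to probabilities and
#' compared with the background: `log2(p / background)`.
#'
#' @param x a [pwm()].
#' @return 4 x L numeric matrix with rownames `A,C,G,T`.
#' @export
pwm_logodds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  p <- sweep(x$counts + x$pseudocount, 2,
             colSums(x$counts + x$pseudocount), "/")
  log2(sweep(p, 1, x$background, "/"))
}

#' Consensus (highest-weight base per position) of a PWM
#' @param x a [pwm()].
#' @return Character string of length L.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read a JASPAR-style plain-text PWM library
#'
#' Parses the standard layout: a `>name` header line followed by four rows
#' `A [ n1 n2 ... ]`, `C [...]`, `G [...]`, `T [...]` (brackets optional).
#' Several motifs may follow each other in one file; order is preserved.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return Named list of [pwm()] objects.
#' @export
read_pwm_library <- function(path, background = rep(0.25, 4),
                             pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_ps("no '>' motif headers found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop_ps("motif '", name, "': expected 4 count rows, found ", length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^\\s*[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(vals)) stop_ps("motif '", name, "': unparsable count row")
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop_ps("motif '", name, "': ragged count rows")
    m <- do.call(rbind, rows)
    rownames(m) <- toupper(substr(trimws(body), 1, 1))
    out[[name]] <- pwm(name, m, background = background,
                       pseudocount = pseudocount)
  }
  out
}
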