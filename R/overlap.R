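#' Cross-tissue peak overlap graph
#'
#' All pairs of peaks from different tissues whose shared nucleotides reach
#' the minimum fractional overlap.  The qualifying rule is symmetric by
#' default (the fraction of *either* peak suffices, as `bedtools intersect
#' -f ... -e` would test); the asymmetric variants are available for
#' reproduction attempts against pipelines that fixed a reference set.
#'
#' @param peaksets list of 2-3 `GRanges` peak sets with distinct `tissue`
#'   labels and unique `peak_id`s.
#' @param min_fraction minimum fractional overlap, inclusive (default 0.05).
#' @param rule `"either"` (default), `"first"` (fraction of the peak from
#'   the earlier peak set must qualify) or `"both"`.
#' @return `data.frame` of edges: `peak_a`, `peak_b`, `tissue_a`,
#'   `tissue_b`, `overlap_bp`, `frac_a`, `frac_b`, with `a` always from the
#'   earlier peak set in `peaksets` order.  `attr(, "tissues")` records the
#'   tissue order.
#' @export
build_overlap_graph <- function(peaksets, min_fraction = 0.05,
                                rule = c("either", "first", "both")) {
  rule <- match.arg(rule)
  tissues <- vapply(peaksets, function(p) unique(p$tissue)[1], "")
  if (anyDuplicated(tissues))
    stop_ps("duplicated tissue label: ", tissues[duplicated(tissues)][1L])
  all_pk <- suppressWarnings(do.call(c, lapply(unname(peaksets), function(p) {
    GenomeInfoDb::seqlengths(p) <- NA
    p
  })))
  if (anyDuplicated(all_pk$peak_id)) stop_ps("peak_ids collide across sets")
  hits <- GenomicRanges::findOverlaps(all_pk, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  set_of <- rep(seq_along(peaksets), lengths(peaksets))
  cross <- set_of[qh] != set_of[sh]
  qh <- qh[cross]; sh <- sh[cross]
  # orient so that a is from the earlier peak set
  swap <- set_of[qh] > set_of[sh]
  tmp <- qh[swap]; qh[swap] <- sh[swap]; sh[swap] <- tmp
  fo <- fractional_overlap(all_pk[qh], all_pk[sh])
  qual <- switch(rule,
    either = pmax(fo$frac_a, fo$frac_b) >= min_fraction,
    first = fo$frac_a >= min_fraction,
    both = pmin(fo$frac_a, fo$frac_b) >= min_fraction)
  out <- data.frame(
    peak_a = all_pk$peak_id[qh], peak_b = all_pk$peak_id[sh],
    tissue_a = all_pk$tissue[qh], tissue_b = all_pk$tissue[sh],
    overlap_bp = fo$overlap_bp, frac_a = fo$frac_a, frac_b = fo$frac_b,
    stringsAsFactors = FALSE)[qual, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tissues") <- unname(tissues)
  out
}

#' Exclusive tissue-sharing groups of peaks
#'
#' Connected components of the overlap graph become clusters; each cluster
#' is labelled by the exact set of tissues present (e.g. `ECC-Limb`), with
#' singleton peaks forming `<tissue>-only` clusters.  Three-way sharing
#' follows transitive chaining: an A-B edge plus a B-C edge places all
#' three peaks in one A-B-C cluster even without a direct A-C edge.  Every
#' peak belongs to exactly one cluster.
#'
#' @param edges from [build_overlap_graph()].
#' @param peaksets the same list of peak sets.
#' @return `data.frame` with one row per peak: `cluster_id`, `peak_id`,
#'   `tissue`, `group`; `attr(, "tissues")` records the tissue order used
#'   in group labels.
#' @export
classify_overlap_groups <- function(edges, peaksets) {
  tissues <- vapply(peaksets, function(p) unique(p$tissue)[1], "")
  ids <- unlist(lapply(peaksets, function(p) p$peak_id), use.names = FALSE)
  tissue_of <- rep(tissues, lengths(peaksets))
  g <- igraph::graph_from_data_frame(
    edges[, c("peak_a", "peak_b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  cluster_id <- sprintf("cluster_%04d", as.integer(factor(comp)))
  out <- data.frame(cluster_id = cluster_id, peak_id = ids,
                    tissue = tissue_of, stringsAsFactors = FALSE)
  grp <- vapply(split(out$tissue, out$cluster_id), function(tt) {
    present <- tissues[tissues %in% tt]
    if (length(present) == 1L) paste0(present, "-only")
    else paste(present, collapse = "-")
  }, "")
  out$group <- unname(grp[out$cluster_id])
  attr(out, "tissues") <- unname(tissues)
  out
}

#' All seven exclusive group labels for a tissue ordering
#' @param tissues character vector of 3 tissue labels.
#' @return Character vector of the 7 group labels.
#' @export
overlap_group_levels <- function(tissues) {
  stopifnot(length(tissues) >= 2)
  combos <- unlist(lapply(seq_along(tissues), function(k)
    utils::combn(tissues, k, function(x)
      if (length(x) == 1L) paste0(x, "-only") else paste(x, collapse = "-"),
      simplify = TRUE)))
  combos
}

#' Shared-peak counts per group under three accounting modes
#'
#' The number printed for a shared group depends on what is enumerated:
#' whole clusters, or the member peaks contributed by the first or second
#' tissue of the group.  All three are reported.
#'
#' @param assignments from [classify_overlap_groups()].
#' @return `data.frame` per group: `group`, `clusters`, `peaks_total`,
#'   `peaks_first`, `peaks_second` (first/second by position of the tissue
#'   in the group label; equal to `peaks_total` for single-tissue groups).
#' @export
shared_peak_counts <- function(assignments) {
  tissues <- attr(assignments, "tissues")
  levels_all <- overlap_group_levels(tissues)
  out <- lapply(levels_all, function(gr) {
    a <- assignments[assignments$group == gr, , drop = FALSE]
    grp_tissues <- if (grepl("-only$", gr)) sub("-only$", "", gr)
                   else strsplit(gr, "-", fixed = TRUE)[[1]]
    data.frame(group = gr,
               clusters = length(unique(a$cluster_id)),
               peaks_total = nrow(a),
               peaks_first = sum(a$tissue == grp_tissues[1L]),
               peaks_second = sum(a$tissue == grp_tissues[min(2L, length(grp_tissues))]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
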