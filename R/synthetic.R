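#' Configuration for the synthetic-data generator
#'
#' Defaults encode the simulated study conditions used throughout the
#' package's tests: three tissues of 200 peaks each with a designed
#' 7-group sharing structure (pairwise and three-way counts scale the
#' ratios seen in multi-tissue Twist1 occupancy comparisons, including 6
#' three-way clusters), peak lengths of 50-750 bp, E-box plant fractions
#' per group echoing observed E-box content of shared binding regions,
#' module spacings straddling the 40-bp window, and ChIP-qPCR panels in
#' biological triplicate.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length, bp.
#' @param n_genes total genes placed (evenly spread over chromosomes).
#' @param gc_content genome GC fraction.
#' @param peak_length_range min/max peak length, bp.
#' @param tissues three tissue labels.
#' @param group_design named counts of clusters per exclusive sharing
#'   group; names are built from `tissues` as in [overlap_group_levels()].
#' @param ebox_plant_fraction named per-group fraction of clusters that
#'   get a planted E-box (`CANNTG`) at the cluster centre.
#' @param module_plant_spacings edge-to-edge gaps (bp) at which a cofactor
#'   consensus is planted next to planted E-boxes, cycled per group.
#' @param expressed_fraction fraction of genes flagged expressed per tissue.
#' @param far_fraction fraction of clusters placed >50 kb from every TSS.
#' @param qpcr_design `data.frame(region_id, antibody, fold, sd)` of true
#'   fold enrichments and Ct noise; triplicate wells are generated.
#' @param n_replicates qPCR replicates per (region, antibody).
#' @param seed integer seed; every generator output is bit-reproducible
#'   given the config.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_chroms = 3,
                         chrom_length = 1800000,
                         n_genes = 330,
                         gc_content = 0.45,
                         peak_length_range = c(50, 750),
                         tissues = c("ECC", "Limb", "PNST"),
                         group_design = NULL,
                         ebox_plant_fraction = NULL,
                         module_plant_spacings = c(0, 20, 40, 41, 100),
                         expressed_fraction = 0.5,
                         far_fraction = 0.4,
                         qpcr_design = NULL,
                         n_replicates = 3,
                         seed = 1L) {
  stopifnot(length(tissues) == 3)
  lv <- overlap_group_levels(tissues)
  if (is.null(group_design)) {
    group_design <- setNames(c(147, 145, 160, 31, 16, 18, 6), lv)
  }
  if (is.null(ebox_plant_fraction)) {
    ebox_plant_fraction <- setNames(
      c(0.7, 0.7, 0.7, 138 / 205, 7 / 10, 6 / 8, 5 / 6), lv)
  }
  if (is.null(qpcr_design)) {
    qpcr_design <- data.frame(
      region_id = c("enriched_region", "null_region"),
      antibody = "target", fold = c(8, 1), sd = c(0.2, 0.2),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_chroms = n_chroms, chrom_length = as.integer(chrom_length),
              n_genes = n_genes, gc_content = gc_content,
              peak_length_range = as.integer(peak_length_range),
              tissues = tissues, group_design = group_design,
              ebox_plant_fraction = ebox_plant_fraction,
              module_plant_spacings = as.integer(module_plant_spacings),
              expressed_fraction = expressed_fraction,
              far_fraction = far_fraction, qpcr_design = qpcr_design,
              n_replicates = n_replicates, seed = as.integer(seed))
  stopifnot(all(group_design >= 0),
            all(names(group_design) %in% lv),
            cfg$peak_length_range[1] > 0,
            cfg$peak_length_range[2] < chrom_length,
            expressed_fraction >= 0, expressed_fraction <= 1,
            far_fraction >= 0, far_fraction <= 1,
            all(ebox_plant_fraction >= 0 & ebox_plant_fraction <= 1))
  structure(cfg, class = "synth_config")
}

rand_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

GENE_PAD <- 10000L
GENE_SPACING <- 10000L
FAR_SPACING <- 5000L
FAR_MARGIN <- 52000L

#' Generate a toy genome with gene models
#'
#' Random sequence at the requested GC content; genes occupy evenly spaced
#' slots in the first part of each chromosome (random strand, 2-4 exons,
#' most with a CDS), leaving a terminal gene-free region in which
#' [generate_peaksets()] can place peaks far from every TSS.
#'
#' @param config a [synth_config()].
#' @return List with `genome` (`DNAStringSet`), `genes` (`gene_models`)
#'   and `layout` (slot bookkeeping consumed by [generate_peaksets()]).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    gpc <- ceiling(config$n_genes / config$n_chroms)
    gene_region_end <- GENE_PAD + gpc * GENE_SPACING
    if (config$n_genes > 0 && gene_region_end > config$chrom_length - 20000L)
      stop_ps("n_genes too dense for chrom_length; increase chrom_length ",
              "to at least ", gene_region_end + 20000L)
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    genome <- setNames(vapply(chroms, function(ch)
      rand_dna(config$chrom_length, config$gc_content), ""), chroms)
    rows <- list()
    slot_tbl <- list()
    gi <- 0L
    for (ci in seq_len(config$n_chroms)) {
      n_here <- min(gpc, config$n_genes - (ci - 1L) * gpc)
      if (n_here <= 0) next
      for (k in seq_len(n_here)) {
        gi <- gi + 1L
        slot_pos <- GENE_PAD + (k - 1L) * GENE_SPACING
        tss <- slot_pos + sample(0:2000, 1L)
        strand <- sample(c("+", "-"), 1L)
        tx_len <- sample(3000:8000, 1L)
        n_ex <- sample(2:4, 1L)
        cuts <- sort(sample(seq(50L, tx_len - 50L), 2L * (n_ex - 1L)))
        rel_s <- c(1L, cuts[seq(2L, length(cuts), by = 2L)] + 1L)
        rel_e <- c(cuts[seq(1L, length(cuts), by = 2L)], tx_len)
        if (strand == "+") {
          tx_start <- tss; tx_end <- tss + tx_len - 1L
        } else {
          tx_end <- tss; tx_start <- tss - tx_len + 1L
        }
        ex_s <- tx_start + rel_s - 1L
        ex_e <- tx_start + rel_e - 1L
        coding <- runif(1) < 0.8
        cds_s <- if (coding) ex_s[1L] + 10L else NA_integer_
        cds_e <- if (coding) ex_e[length(ex_e)] - 10L else NA_integer_
        rows[[gi]] <- list(gene = sprintf("Gene%03d", gi), chrom = chroms[ci],
                           strand = strand, tss = tss, tx_start = tx_start,
                           tx_end = tx_end, exon_starts = ex_s,
                           exon_ends = ex_e, cds_start = cds_s,
                           cds_end = cds_e)
        slot_tbl[[gi]] <- data.frame(gene = sprintf("Gene%03d", gi),
                                     chrom = chroms[ci], slot_pos = slot_pos,
                                     tss = tss, stringsAsFactors = FALSE)
      }
    }
    genes <- if (gi > 0)
      gene_models(
        gene = vapply(rows, `[[`, "", "gene"),
        chrom = vapply(rows, `[[`, "", "chrom"),
        strand = vapply(rows, `[[`, "", "strand"),
        tss = vapply(rows, `[[`, 0L, "tss"),
        tx_start = vapply(rows, `[[`, 0L, "tx_start"),
        tx_end = vapply(rows, `[[`, 0L, "tx_end"),
        exon_starts = lapply(rows, `[[`, "exon_starts"),
        exon_ends = lapply(rows, `[[`, "exon_ends"),
        cds_start = vapply(rows, `[[`, NA_integer_, "cds_start"),
        cds_end = vapply(rows, `[[`, NA_integer_, "cds_end"))
    else gene_models(character(), character(), character(), integer(),
                     integer(), integer(), list(), list())
    last_tss <- vapply(sprintf("chr%d", seq_len(config$n_chroms)),
                       function(ch) {
      st <- do.call(rbind, slot_tbl)
      if (is.null(st) || !any(st$chrom == ch)) return(0L)
      max(st$tss[st$chrom == ch])
    }, 0L)
    list(genome = Biostrings::DNAStringSet(genome), genes = genes,
         layout = list(slots = do.call(rbind, slot_tbl),
                       last_tss = last_tss,
                       chrom_length = config$chrom_length,
                       chroms = sprintf("chr%d", seq_len(config$n_chroms))))
  })
}

#' Built-in toy cofactor PWMs
#'
#' Two sharp example matrices used by the synthetic generator and the
#' bundled PWM library file: a nuclear-receptor-like half site
#' (`RXR_like`, consensus `AGGTCA`) and a C-rich zinc-finger-like site
#' (`RREB_like`, consensus `CCCCAAAC`).  The same matrices ship as
#' `inst/extdata/cofactor_pwms.txt` in JASPAR text form.
#'
#' @return Named list of two [pwm()] objects.
#' @export
default_cofactor_pwms <- function() {
  rxr <- pwm("RXR_like", matrix(c(
    95,  2,  1,  2,  2,  3,
     1,  1,  1,  1, 94,  2,
     2, 95, 96,  2,  2,  2,
     2,  2,  2, 95,  2, 93), nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), NULL)))
  rreb <- pwm("RREB_like", matrix(c(
     2,  2,  2,  2, 94, 94, 95,  2,
    94, 95, 94, 95,  2,  2,  2, 94,
     2,  1,  2,  1,  2,  2,  1,  2,
     2,  2,  2,  2,  2,  2,  2,  2), nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), NULL)))
  list(RXR_like = rxr, RREB_like = rreb)
}

# Lean region scanner used only while scrubbing: finds CANNTG starts and
# above-threshold PWM windows (both strands) by direct index arithmetic,
# independently of the scan_consensus()/scan_pwm() code paths.
region_motif_hits <- function(sub, lo, thr) {
  v <- match(strsplit(sub, "")[[1]], c("A", "C", "G", "T"))
  n <- length(v)
  hits <- NULL
  if (n >= 6L) {
    p <- seq_len(n - 5L)
    eb <- p[!is.na(v[p]) & v[p] == 2L & v[p + 1L] == 1L &
              !is.na(v[p + 4L]) & v[p + 4L] == 4L & v[p + 5L] == 3L]
    if (length(eb))
      hits <- data.frame(start = eb, end = eb + 5L, motif = "CANNTG",
                         stringsAsFactors = FALSE)
  }
  L <- ncol(lo)
  if (n >= L) {
    p <- seq_len(n - L + 1L)
    fwd <- rep(0, length(p)); rev <- rep(0, length(p))
    comp <- c(4L, 3L, 2L, 1L)
    for (j in seq_len(L)) {
      fwd <- fwd + lo[cbind(v[p + j - 1L], j)]
      rev <- rev + lo[cbind(comp[v[p + L - j]], j)]
    }
    pw <- p[(!is.na(fwd) & fwd >= thr) | (!is.na(rev) & rev >= thr)]
    if (length(pw))
      hits <- rbind(hits, data.frame(start = pw, end = pw + L - 1L,
                                     motif = "pwm",
                                     stringsAsFactors = FALSE))
  }
  hits %||% data.frame(start = integer(), end = integer(),
                       motif = character(), stringsAsFactors = FALSE)
}

# Mutate bases until the window [s, e] of `seq_str` carries no consensus or
# above-threshold PWM hit outside the protected intervals.  Offending
# windows are neutralised by rewriting their unprotected positions with
# A/C-only bases: without G or T neither CANNTG nor the planted cofactor
# consensus (on either strand) can reassemble, so progress is monotone.
scrub_region <- function(sub, cof, rel_threshold,
                         protected = NULL, max_iter = 30L) {
  lo <- pwm_logodds(cof)
  thr <- pwm_score_range(cof, rel_threshold)[["threshold"]]
  for (iter in seq_len(max_iter)) {
    hits <- region_motif_hits(sub, lo, thr)
    if (!is.null(protected) && nrow(hits)) {
      planted <- vapply(seq_len(nrow(hits)), function(j) {
        any(protected$start == hits$start[j] & protected$end == hits$end[j] &
              protected$motif == hits$motif[j])
      }, TRUE)
      hits <- hits[!planted, , drop = FALSE]
    }
    if (!nrow(hits)) return(sub)
    changed <- FALSE
    prot_pos <- if (is.null(protected)) integer() else
      unlist(mapply(seq, protected$start, protected$end, SIMPLIFY = FALSE))
    for (j in seq_len(nrow(hits))) {
      cand <- setdiff(seq(hits$start[j], hits$end[j]), prot_pos)
      if (!length(cand)) next  # fully inside planted material; harmless
      for (p in cand)
        substr(sub, p, p) <- sample(c("A", "C"), 1L)
      changed <- TRUE
    }
    if (!changed) return(sub)  # only unremovable hits remain
  }
  stop_ps("motif scrubbing did not converge")
}

#' Generate three tissue peak sets with a designed sharing structure
#'
#' Clusters are placed with guard gaps so that peaks of the same cluster
#' share well over 5% of their nucleotides while peaks of different
#' clusters never overlap.  A designed fraction of clusters sits >50 kb
#' from every TSS; the rest sit 1-10 kb from a gene.  E-boxes and cofactor
#' consensus sites are planted by overwriting genome bases at recorded
#' offsets and spacings, and incidental motif occurrences are scrubbed
#' from the (extended) peak regions so that planted content is the only
#' motif signal.
#'
#' @param config a [synth_config()].
#' @param genome_bundle output of [generate_genome()].
#' @param cofactor [pwm()] planted as the module partner (default the
#'   built-in `RXR_like`).
#' @param rel_threshold PWM threshold used when scrubbing (default 0.8,
#'   matching the scanner default).
#' @return List: `peaksets` (named list of 3 annotated `GRanges`),
#'   `genome` (motif-planted `DNAStringSet`), `truth` (cluster table,
#'   per-group counts, planted E-box/module records).
#' @export
generate_peaksets <- function(config, genome_bundle,
                              cofactor = default_cofactor_pwms()$RXR_like,
                              rel_threshold = 0.8) {
  stopifnot(inherits(config, "synth_config"))
  layout <- genome_bundle$layout
  gd <- config$group_design
  n_clusters <- sum(gd)
  with_seed(config$seed + 1L, {
    cl <- data.frame(cluster = sprintf("cl%04d", seq_len(n_clusters)),
                     group = rep(names(gd), gd), stringsAsFactors = FALSE)
    cl <- cl[sample(nrow(cl)), , drop = FALSE]
    rownames(cl) <- NULL
    n_far <- round(config$far_fraction * n_clusters)
    cl$far <- seq_len(n_clusters) %in% sample(n_clusters, n_far)
    slots <- layout$slots
    if (sum(!cl$far) > nrow(slots))
      stop_ps("design infeasible: ", sum(!cl$far), " near clusters but only ",
              nrow(slots), " gene slots; increase n_genes or chrom_length")
    near_slots <- slots[sample(nrow(slots), sum(!cl$far)), , drop = FALSE]
    # centres for near clusters: inside the assigned gene's slot territory
    cl$chrom <- NA_character_; cl$center <- NA_integer_
    cl$chrom[!cl$far] <- near_slots$chrom
    cl$center[!cl$far] <- near_slots$slot_pos +
      sample(3500:8800, sum(!cl$far), replace = TRUE)
    # far clusters: spaced slots in the terminal gene-free region
    far_idx <- which(cl$far)
    if (length(far_idx)) {
      per_chrom <- split(far_idx,
                         rep_len(seq_along(layout$chroms), length(far_idx)))
      for (ci in seq_along(layout$chroms)) {
        idx <- per_chrom[[as.character(ci)]]
        if (is.null(idx) || !length(idx)) next
        start0 <- layout$last_tss[ci] + FAR_MARGIN
        centers <- start0 + (seq_along(idx) - 1L) * FAR_SPACING
        if (max(centers) > layout$chrom_length - 2000L)
          stop_ps("design infeasible: far clusters exceed chromosome; ",
                  "increase chrom_length")
        cl$chrom[idx] <- layout$chroms[ci]
        cl$center[idx] <- centers
      }
    }
    # peaks per cluster
    tissues_of_group <- function(g) {
      if (grepl("-only$", g)) sub("-only$", "", g)
      else strsplit(g, "-", fixed = TRUE)[[1]]
    }
    lr <- config$peak_length_range
    peak_rows <- list()
    for (i in seq_len(nrow(cl))) {
      for (tt in tissues_of_group(cl$group[i])) {
        len <- sample(lr[1]:lr[2], 1L)
        jit <- sample(-20:20, 1L)
        st <- cl$center[i] - len %/% 2L + jit
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          cluster = cl$cluster[i], group = cl$group[i], tissue = tt,
          chrom = cl$chrom[i], start = st, end = st + len - 1L,
          summit = cl$center[i] - st, stringsAsFactors = FALSE)
      }
    }
    pk <- do.call(rbind, peak_rows)
    pk$tags <- sample(20:300, nrow(pk), replace = TRUE)
    pk$pvalue_score <- round(runif(nrow(pk), 55, 310), 2)
    pk$fold_enrichment <- round(runif(nrow(pk), 2, 60), 2)
    pk$peak_id <- stats::ave(seq_len(nrow(pk)), pk$tissue,
                             FUN = seq_along)
    pk$peak_id <- sprintf("%s_pk%04d", pk$tissue, pk$peak_id)
    # ---- motif scrubbing and planting ------------------------------------
    genome_chr <- setNames(as.character(genome_bundle$genome),
                           names(genome_bundle$genome))
    ebox_plant <- config$ebox_plant_fraction
    spac <- config$module_plant_spacings
    cl$ebox <- FALSE
    cl$module_gap <- NA_integer_
    for (g in unique(cl$group)) {
      idx <- which(cl$group == g)
      frac <- unname(ebox_plant[g])
      if (is.na(frac)) frac <- 0
      k <- round(frac * length(idx))
      if (k > 0) {
        chosen <- idx[sample(length(idx), k)]
        cl$ebox[chosen] <- TRUE
        if (length(spac))
          cl$module_gap[chosen] <- rep_len(spac, length(chosen))
      }
    }
    cof_cons <- pwm_consensus(cofactor)
    Lc <- nchar(cof_cons)
    planted <- list()
    cluster_min <- tapply(pk$start, pk$cluster, min)
    cluster_max <- tapply(pk$end, pk$cluster, max)
    for (i in seq_len(nrow(cl))) {
      ch <- cl$chrom[i]
      # region to scrub: extended extent of the cluster's peaks
      rs <- unname(cluster_min[cl$cluster[i]]) - 205L
      re <- unname(cluster_max[cl$cluster[i]]) + 205L
      region <- scrub_region(substr(genome_chr[[ch]], rs, re),
                             cofactor, rel_threshold)
      if (cl$ebox[i]) {
        es <- cl$center[i] - 3L
        nn <- paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                    collapse = "")
        substr(region, es - rs + 1L, es - rs + 6L) <- paste0("CA", nn, "TG")
        prot <- data.frame(start = es - rs + 1L, end = es - rs + 6L,
                           motif = "CANNTG", stringsAsFactors = FALSE)
        if (!is.na(cl$module_gap[i])) {
          cs <- es + 6L + cl$module_gap[i]
          substr(region, cs - rs + 1L, cs - rs + Lc) <- cof_cons
          prot <- rbind(prot, data.frame(start = cs - rs + 1L,
                                         end = cs - rs + Lc,
                                         motif = "pwm",
                                         stringsAsFactors = FALSE))
          planted[[length(planted) + 1L]] <- data.frame(
            cluster = cl$cluster[i], chrom = ch, ebox_start = es,
            cofactor_start = cs, gap = cl$module_gap[i],
            stringsAsFactors = FALSE)
        } else {
          planted[[length(planted) + 1L]] <- data.frame(
            cluster = cl$cluster[i], chrom = ch, ebox_start = es,
            cofactor_start = NA_integer_, gap = NA_integer_,
            stringsAsFactors = FALSE)
        }
        # re-scrub around planted material, protecting it
        region <- scrub_region(region, cofactor, rel_threshold,
                               protected = prot)
      }
      substr(genome_chr[[ch]], rs, re) <- region
    }
    genome <- Biostrings::DNAStringSet(genome_chr)
    sizes <- setNames(Biostrings::width(genome), names(genome))
    peaksets <- lapply(setNames(config$tissues, config$tissues),
                       function(tt) {
      p <- pk[pk$tissue == tt, , drop = FALSE]
      gr <- make_intervals(p$chrom, p$start, p$end, chrom_sizes = sizes)
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        peak_id = p$peak_id, tissue = tt, summit = p$summit,
        tags = p$tags, pvalue_score = p$pvalue_score,
        fold_enrichment = p$fold_enrichment,
        down_gene = NA_character_, down_dist = NA_real_,
        up_gene = NA_character_, up_dist = NA_real_)
      if (nrow(genome_bundle$genes))
        gr <- annotate_peaks(gr, genome_bundle$genes)
      gr
    })
    group_counts <- table(factor(cl$group,
                                 levels = overlap_group_levels(config$tissues)))
    ebox_by_group <- vapply(split(cl$ebox, cl$group), sum, 0L)
    truth <- list(
      clusters = cl, peaks = pk,
      group_counts = setNames(as.integer(group_counts),
                              names(group_counts)),
      ebox_clusters_by_group = ebox_by_group,
      planted = if (length(planted)) do.call(rbind, planted) else NULL,
      module_spacings = spac,
      cofactor = cofactor$name)
    list(peaksets = peaksets, genome = genome, truth = truth)
  })
}

#' Generate expressed-gene labels per tissue
#'
#' @param config a [synth_config()].
#' @param genes `gene_models`.
#' @return List: `expression` (named list of `expression_set`), `truth`
#'   (logical gene x tissue flag matrix).
#' @export
generate_expression <- function(config, genes) {
  with_seed(config$seed + 2L, {
    flags <- matrix(runif(nrow(genes) * length(config$tissues)) <
                      config$expressed_fraction,
                    nrow = nrow(genes),
                    dimnames = list(genes$gene, config$tissues))
    expr <- lapply(setNames(config$tissues, config$tissues), function(tt)
      expression_set(tt, rownames(flags)[flags[, tt]]))
    list(expression = expr, truth = flags)
  })
}

#' Generate a ChIP-qPCR Ct panel with known fold enrichments
#'
#' Antibody wells get `Ct = baseline - log2(fold) + noise`, IgG wells
#' `Ct = baseline + noise`; a fixed per-region input Ct is attached so the
#' input normalisation cancels exactly.  With zero noise the designed fold
#' is recovered exactly by [compute_fold_enrichment()].
#'
#' @param config a [synth_config()] (`qpcr_design`, `n_replicates`, `seed`).
#' @return List: `table` (`qpcr_table`), `truth` (the design).
#' @export
generate_qpcr <- function(config) {
  with_seed(config$seed + 3L, {
    des <- config$qpcr_design
    nrep <- config$n_replicates
    rows <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
      baseline <- runif(1, 28, 32)
      input_ct <- runif(1, 24, 26)
      data.frame(
        region_id = des$region_id[i],
        antibody = rep(c(des$antibody[i], "IgG"), each = nrep),
        replicate = rep(seq_len(nrep), 2L),
        ct = c(baseline - log2(des$fold[i]) + rnorm(nrep, 0, des$sd[i]),
               baseline + rnorm(nrep, 0, des$sd[i])),
        input_ct = input_ct, stringsAsFactors = FALSE)
    }))
    list(table = qpcr_table(rows$region_id, rows$antibody, rows$replicate,
                            rows$ct, rows$input_ct),
         truth = des)
  })
}

# The generator's own nearest-TSS bookkeeping (independent of
# assign_nearest_genes): for each peak, the two nearest TSSs by direction.
synth_nearest <- function(pk, genes) {
  res <- data.frame(peak_id = pk$peak_id, min_dist = NA_real_,
                    gene_down = NA_character_, gene_up = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pk))) {
    g <- genes[genes$chrom == pk$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- ifelse(g$tss >= pk$start[i] & g$tss <= pk$end[i], 0,
                ifelse(g$tss > pk$end[i], g$tss - pk$end[i],
                       g$tss - pk$start[i]))
    down <- which(d >= 0); up <- which(d <= 0)
    if (length(down)) {
      j <- down[which.min(abs(d[down]))]
      res$gene_down[i] <- g$gene[j]
    }
    if (length(up)) {
      j <- up[which.min(abs(d[up]))]
      res$gene_up[i] <- g$gene[j]
    }
    res$min_dist[i] <- min(abs(d))
  }
  res
}

#' Generate a complete synthetic study bundle
#'
#' Runs all generators and derives the ground-truth peak cascade (total,
#' within 50 kb of a TSS, associated with an expressed gene) per tissue
#' from the generator's own layout bookkeeping.  Optionally writes every
#' file the pipeline readers consume, plus `ground_truth.json`.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, `genome.fa`, `genes.tsv`,
#'   `peaks_<tissue>.tsv`, `expressed_<tissue>.txt`, `qpcr.csv`,
#'   `cofactor_pwms.txt` and `ground_truth.json` are written there.
#' @return List: `config`, `genome`, `genes`, `peaksets`, `expression`,
#'   `qpcr`, `truth` (with `$cascade` per tissue), and `dir` when written.
#' @export
generate_bundle <- function(config = synth_config(), dir = NULL) {
  gb <- generate_genome(config)
  ps <- generate_peaksets(config, gb)
  ex <- generate_expression(config, gb$genes)
  qp <- generate_qpcr(config)
  near <- synth_nearest(ps$truth$peaks, gb$genes)
  cascade <- lapply(setNames(config$tissues, config$tissues), function(tt) {
    idx <- ps$truth$peaks$tissue == tt
    nr <- near[idx, , drop = FALSE]
    within <- !is.na(nr$min_dist) & nr$min_dist <= 50000
    expr_genes <- ex$expression[[tt]]$genes
    expressed <- within &
      (toupper(nr$gene_down) %in% expr_genes |
         toupper(nr$gene_up) %in% expr_genes)
    expressed[is.na(expressed)] <- FALSE
    list(total = sum(idx), within_50kb = sum(within),
         expressed = sum(expressed),
         surviving_peaks = nr$peak_id[expressed])
  })
  truth <- c(ps$truth, list(cascade = cascade, expression = ex$truth,
                            qpcr = qp$truth))
  bundle <- list(config = config, genome = ps$genome, genes = gb$genes,
                 peaksets = ps$peaksets, expression = ex$expression,
                 qpcr = qp$table, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(bundle$genome, file.path(dir, "genome.fa"))
    write_gene_models(bundle$genes, file.path(dir, "genes.tsv"))
    for (tt in config$tissues) {
      write_macs_peaks(bundle$peaksets[[tt]],
                       file.path(dir, sprintf("peaks_%s.tsv", tt)))
      writeLines(bundle$expression[[tt]]$genes,
                 file.path(dir, sprintf("expressed_%s.txt", tt)))
    }
    write.table(bundle$qpcr, file.path(dir, "qpcr.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    file.copy(system.file("extdata", "cofactor_pwms.txt",
                          package = "peakshare"),
              file.path(dir, "cofactor_pwms.txt"), overwrite = TRUE)
    truth_json <- truth
    truth_json$cascade <- lapply(truth$cascade, function(x)
      x[c("total", "within_50kb", "expressed")])
    jsonlite::write_json(
      list(group_counts = as.list(truth$group_counts),
           ebox_clusters_by_group = as.list(truth$ebox_clusters_by_group),
           cascade = truth_json$cascade,
           module_spacings = truth$module_spacings),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
    bundle$dir <- dir
  }
  bundle
}
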