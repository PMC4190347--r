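#' Assemble a pipeline configuration
#'
#' Collects input paths and analysis parameters.  Peaks are required; the
#' other inputs are optional and the corresponding stages degrade
#' gracefully (the cascade stops after the 50-kb stage without expression
#' lists; motif stages are skipped without a genome).
#'
#' @param peaks named list/vector: tissue label -> MACS-style table path.
#' @param genes gene-model table path.
#' @param genome genome FASTA path.
#' @param expression named list/vector: tissue -> expressed-gene list path.
#' @param pwms JASPAR-style PWM library path (cofactors for modules).
#' @param qpcr qPCR CSV path.
#' @param tss_threshold bp, inclusive (default 50000).
#' @param min_fraction minimum fractional overlap (default 0.05).
#' @param extension bp added per side before sequence extraction (200).
#' @param max_gap module spacing window, bp (default 40).
#' @param rel_threshold PWM range-relative threshold (default 0.8).
#' @param n_shuffles shuffles for the enrichment z (default 100).
#' @param alpha qPCR significance level (default 0.05).
#' @param seed seed for the shuffle background.
#' @param overlap_rule `"either"`, `"first"` or `"both"` (see
#'   [build_overlap_graph()]).
#' @param distances `"table"` (use the peak tables' nearest-gene distance
#'   columns) or `"computed"` (recompute from the gene models).
#' @param run_enrichment compute the shuffle-based module z (slowest
#'   stage; default TRUE).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(peaks, genes = NULL, genome = NULL,
                            expression = NULL, pwms = NULL, qpcr = NULL,
                            tss_threshold = 50000, min_fraction = 0.05,
                            extension = 200, max_gap = 40,
                            rel_threshold = 0.8, n_shuffles = 100,
                            alpha = 0.05, seed = 1L,
                            overlap_rule = "either",
                            distances = c("table", "computed"),
                            run_enrichment = TRUE) {
  stopifnot(tss_threshold > 0, min_fraction > 0, extension >= 0,
            max_gap >= 0, rel_threshold > 0, n_shuffles >= 10, alpha > 0)
  structure(list(peaks = peaks, genes = genes, genome = genome,
                 expression = expression, pwms = pwms, qpcr = qpcr,
                 tss_threshold = tss_threshold, min_fraction = min_fraction,
                 extension = extension, max_gap = max_gap,
                 rel_threshold = rel_threshold, n_shuffles = n_shuffles,
                 alpha = alpha, seed = as.integer(seed),
                 overlap_rule = overlap_rule,
                 distances = match.arg(distances),
                 run_enrichment = isTRUE(run_enrichment)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s arguments: `inputs:` (peaks,
#' genes, genome, expression, pwms, qpcr) and `params:` blocks; relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(pp)
      if (file.exists(pp)) pp else file.path(base, pp), "")
  }
  args <- c(list(peaks = fix(y$inputs$peaks),
                 genes = fix(y$inputs$genes),
                 genome = fix(y$inputs$genome),
                 expression = fix(y$inputs$expression),
                 pwms = fix(y$inputs$pwms),
                 qpcr = fix(y$inputs$qpcr)),
            y$params %||% list())
  do.call(pipeline_config, args)
}

#' Pipeline configuration for a written synthetic bundle directory
#' @param dir directory written by [generate_bundle()].
#' @param tissues tissue labels used when writing the bundle.
#' @param ... parameter overrides passed to [pipeline_config()].
#' @export
bundle_config <- function(dir, tissues = c("ECC", "Limb", "PNST"), ...) {
  pipeline_config(
    peaks = setNames(file.path(dir, sprintf("peaks_%s.tsv", tissues)),
                     tissues),
    genes = file.path(dir, "genes.tsv"),
    genome = file.path(dir, "genome.fa"),
    expression = setNames(file.path(dir, sprintf("expressed_%s.txt", tissues)),
                          tissues),
    pwms = file.path(dir, "cofactor_pwms.txt"),
    qpcr = file.path(dir, "qpcr.csv"),
    ...)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_ps("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full multi-tissue comparison pipeline
#'
#' Per tissue: peak cascade (total, within the TSS window, associated with
#' an expressed gene); tissue-sharing groups both before (post-TSS-filter)
#' and after the expression filter, with shared counts under all three
#' accounting modes; genomic-location distributions; per-group E-box
#' summaries; E-box/cofactor modules and their shuffle enrichment;
#' qPCR fold enrichment and t-tests.  With `outdir`, fixed-name report
#' files (`summary.json`, `cascade.tsv`, `groups.tsv`, `ebox.tsv`,
#' `modules.tsv`, `locations.tsv`, `qpcr.tsv`) are written, with a
#' provenance block (parameters, seed, input checksums) in the JSON.
#'
#' @param config a `pipeline_config` or the path to its YAML form.
#' @param outdir optional output directory.
#' @return List of result tables (invisibly also written to `outdir`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- stage("read-inputs", {
    list(
      peaksets = lapply(setNames(names(config$peaks), names(config$peaks)),
                        function(tt) read_macs_peaks(config$peaks[[tt]], tt)),
      genes = if (!is.null(config$genes)) read_gene_models(config$genes),
      genome = if (!is.null(config$genome)) read_genome_fasta(config$genome),
      expression = if (!is.null(config$expression))
        lapply(setNames(names(config$expression), names(config$expression)),
               function(tt) read_expression_list(config$expression[[tt]], tt)),
      pwms = if (!is.null(config$pwms)) read_pwm_library(config$pwms),
      qpcr = if (!is.null(config$qpcr)) read_qpcr_table(config$qpcr))
  })
  run_pipeline_core(inputs, config, outdir)
}

run_pipeline_core <- function(inputs, config, outdir = NULL) {
  tissues <- names(inputs$peaksets)
  # ---- cascade ----------------------------------------------------------
  cascade <- stage("cascade", {
    do.call(rbind, lapply(tissues, function(tt) {
      pk <- inputs$peaksets[[tt]]
      within <- filter_tss_distance(pk, threshold = config$tss_threshold,
                                    distances = config$distances,
                                    genes = inputs$genes)
      if (!is.null(inputs$expression) && !is.null(inputs$genes)) {
        assoc <- assign_nearest_genes(within, inputs$genes,
                                      threshold = config$tss_threshold)
        surv <- filter_by_expression(within, assoc,
                                     inputs$expression[[tt]])
        data.frame(tissue = tt, total = length(pk),
                   within_tss = length(within),
                   expressed = length(surv$peaks),
                   expressed_genes = length(surv$genes),
                   note = "", stringsAsFactors = FALSE)
      } else {
        data.frame(tissue = tt, total = length(pk),
                   within_tss = length(within),
                   expressed = NA_integer_, expressed_genes = NA_integer_,
                   note = "expression filter skipped",
                   stringsAsFactors = FALSE)
      }
    }))
  })
  filtered <- stage("tss-filter", {
    lapply(setNames(tissues, tissues), function(tt)
      filter_tss_distance(inputs$peaksets[[tt]],
                          threshold = config$tss_threshold,
                          distances = config$distances,
                          genes = inputs$genes))
  })
  expressed_sets <- NULL
  if (!is.null(inputs$expression) && !is.null(inputs$genes)) {
    expressed_sets <- stage("expression-filter", {
      lapply(setNames(tissues, tissues), function(tt) {
        assoc <- assign_nearest_genes(filtered[[tt]], inputs$genes,
                                      threshold = config$tss_threshold)
        filter_by_expression(filtered[[tt]], assoc,
                             inputs$expression[[tt]])$peaks
      })
    })
  }
  # ---- overlaps, before and after the expression filter -----------------
  group_stage <- function(sets) {
    edges <- build_overlap_graph(sets, min_fraction = config$min_fraction,
                                 rule = config$overlap_rule)
    asg <- classify_overlap_groups(edges, sets)
    list(edges = edges, assignments = asg,
         counts = shared_peak_counts(asg))
  }
  groups_pre <- stage("overlap-pre-expression", group_stage(filtered))
  groups_post <- if (!is.null(expressed_sets))
    stage("overlap-post-expression", group_stage(expressed_sets))
  # ---- locations --------------------------------------------------------
  locations <- if (!is.null(inputs$genes)) stage("locations", {
    sets <- expressed_sets %||% filtered
    do.call(rbind, lapply(tissues, function(tt) {
      d <- location_distribution(sets[[tt]], inputs$genes)
      d$tissue <- tt
      d
    }))
  })
  # ---- motifs -----------------------------------------------------------
  ebox <- modules <- enrichment <- NULL
  if (!is.null(inputs$genome)) {
    final_sets <- expressed_sets %||% filtered
    all_pk <- suppressWarnings(do.call(c, unname(final_sets)))
    seqs <- stage("sequences",
                  peak_sequences(all_pk, inputs$genome,
                                 extend = config$extension))
    asg <- (groups_post %||% groups_pre)$assignments
    assoc_all <- if (!is.null(inputs$genes))
      assign_nearest_genes(all_pk, inputs$genes,
                           threshold = config$tss_threshold)
    ebox <- stage("ebox-summary",
                  ebox_summary(asg, seqs, assoc = assoc_all))
    if (!is.null(inputs$pwms)) {
      ebox_hits <- scan_consensus(seqs)
      modules <- stage("modules", {
        do.call(rbind, lapply(inputs$pwms, function(pw) {
          m <- find_modules(ebox_hits,
                            scan_pwm(seqs, pw, config$rel_threshold),
                            max_gap = config$max_gap)
          m
        }))
      })
      if (config$run_enrichment) {
        enrichment <- stage("module-enrichment", {
          lapply(inputs$pwms, function(pw)
            module_enrichment(seqs, pw, max_gap = config$max_gap,
                              rel_threshold = config$rel_threshold,
                              n_shuffles = config$n_shuffles,
                              seed = config$seed))
        })
      }
    }
  }
  # ---- qPCR -------------------------------------------------------------
  qpcr <- if (!is.null(inputs$qpcr))
    stage("qpcr", test_enrichment(inputs$qpcr, alpha = config$alpha))
  results <- list(cascade = cascade,
                  groups_pre = groups_pre$counts,
                  groups_post = if (!is.null(groups_post)) groups_post$counts,
                  assignments_pre = groups_pre$assignments,
                  assignments_post = if (!is.null(groups_post))
                    groups_post$assignments,
                  locations = locations, ebox = ebox, modules = modules,
                  enrichment = enrichment, qpcr = qpcr,
                  params = config[setdiff(names(config),
                                          c("peaks", "genes", "genome",
                                            "expression", "pwms", "qpcr"))])
  if (!is.null(outdir)) write_pipeline_reports(results, config, outdir)
  results
}

write_pipeline_reports <- function(results, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    if (!is.null(df))
      write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  tsv(results$cascade, "cascade.tsv")
  grp <- results$groups_pre
  grp$stage <- "pre-expression"
  if (!is.null(results$groups_post)) {
    g2 <- results$groups_post
    g2$stage <- "post-expression"
    grp <- rbind(grp, g2)
  }
  tsv(grp, "groups.tsv")
  tsv(results$locations, "locations.tsv")
  tsv(results$ebox, "ebox.tsv")
  tsv(results$modules, "modules.tsv")
  tsv(results$qpcr, "qpcr.tsv")
  input_files <- unlist(config[c("peaks", "genes", "genome", "expression",
                                 "pwms", "qpcr")], use.names = TRUE)
  checksums <- if (length(input_files) && all(file.exists(input_files)))
    as.list(tools::md5sum(input_files)) else NULL
  summary <- list(
    cascade = results$cascade,
    shared_counts = list(
      pre_expression = results$groups_pre,
      post_expression = results$groups_post),
    ebox = results$ebox,
    enrichment = lapply(results$enrichment, unclass),
    qpcr = results$qpcr,
    provenance = list(parameters = results$params,
                      checksums = checksums))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}
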