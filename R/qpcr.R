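delta_delta_ct <- function(tab, region) {
  t_r <- tab[tab$region_id == region, , drop = FALSE]
  if (!nrow(t_r)) stop_ps("no qPCR rows for region '", region, "'")
  igg <- is_igg(t_r$antibody)
  if (!any(igg)) stop_ps("region '", region, "' has no IgG control rows")
  dct <- t_r$ct - t_r$input_ct
  igg_mean <- mean(dct[igg])
  split(dct - igg_mean, t_r$antibody)
}

#' ChIP-qPCR fold enrichment relative to the IgG control
#'
#' Per replicate, `dCt = Ct - input_Ct`; per antibody,
#' `ddCt_r = dCt_r - mean(dCt(IgG))`; fold = `2^(-mean(ddCt))`.  The IgG
#' control processed the same way yields fold 1.0 exactly.  With the
#' `"no-input"` table dialect `input_Ct` is 0, so `dCt = Ct` and the IgG
#' subtraction still cancels plate effects.
#'
#' @param tab a `qpcr_table` (see [read_qpcr_table()]).
#' @param region region id; default all regions.
#' @return `data.frame` per (region, antibody): `region_id`, `antibody`,
#'   `n_replicates`, `mean_ddct`, `fold`.
#' @export
compute_fold_enrichment <- function(tab, region = NULL) {
  regions <- region %||% unique(tab$region_id)
  out <- do.call(rbind, lapply(regions, function(r) {
    dd <- delta_delta_ct(tab, r)
    data.frame(region_id = r, antibody = names(dd),
               n_replicates = lengths(dd),
               mean_ddct = vapply(dd, mean, 0),
               fold = 2^(-vapply(dd, mean, 0)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  # exact identity for the control, immune to floating-point residue
  out$fold[is_igg(out$antibody)] <- 1.0
  out$mean_ddct[is_igg(out$antibody)] <- 0
  out
}

#' Student t-test on ChIP-qPCR ddCt values versus the IgG control
#'
#' Two-sample, two-sided, equal-variance by default (Welch via
#' `var_equal = FALSE`), comparing each antibody's per-replicate ddCt
#' values with the IgG control's.  Degenerate inputs: identical constant
#' groups give p = 1; constant groups with unequal means give the p = 0
#' sentinel with a warning.
#'
#' @inheritParams compute_fold_enrichment
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param var_equal pool variances (classical Student t) when `TRUE`.
#' @return `data.frame` as [compute_fold_enrichment()] plus `t_stat`,
#'   `p_value`, `significant`; IgG rows carry NA test fields.
#' @export
test_enrichment <- function(tab, region = NULL, alpha = 0.05,
                            var_equal = TRUE) {
  folds <- compute_fold_enrichment(tab, region)
  regions <- region %||% unique(tab$region_id)
  tests <- do.call(rbind, lapply(regions, function(r) {
    dd <- delta_delta_ct(tab, r)
    igg_vals <- unlist(dd[is_igg(names(dd))], use.names = FALSE)
    do.call(rbind, lapply(names(dd), function(ab) {
      if (is_igg(ab))
        return(data.frame(region_id = r, antibody = ab, t_stat = NA_real_,
                          p_value = NA_real_, stringsAsFactors = FALSE))
      x <- dd[[ab]]
      if (length(x) < 2L || length(igg_vals) < 2L)
        stop_ps("region '", r, "', antibody '", ab,
                "': need >= 2 replicates per class for the t-test")
      if (sd(x) == 0 && sd(igg_vals) == 0) {
        if (isTRUE(all.equal(mean(x), mean(igg_vals)))) {
          tt <- list(statistic = 0, p.value = 1)
        } else {
          warn_ps("region '", r, "': zero variance with unequal means; ",
                  "p = 0 sentinel")
          tt <- list(statistic = sign(mean(x) - mean(igg_vals)) * Inf,
                     p.value = 0)
        }
      } else {
        ht <- t.test(x, igg_vals, var.equal = var_equal)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      data.frame(region_id = r, antibody = ab, t_stat = tt$statistic,
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    }))
  }))
  out <- merge(folds, tests, by = c("region_id", "antibody"), sort = FALSE)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$significant[is_igg(out$antibody)] <- NA
  out
}
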