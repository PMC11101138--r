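# Aggregation of per-stimulation records across cross-validation folds and
# the stratified analyses.

#' Aggregate metrics across cross-validation folds
#'
#' For each group, per-stimulation records are first averaged within each
#' fold, then the mean and the 95\% half-width of the standard error of the
#' mean (`1.96 * sd / sqrt(n_folds)`) are taken over the fold means. Records
#' with undefined metrics (NA) are excluded. A group with a single fold gets
#' `sem_95 = 0` and is flagged `degenerate`.
#'
#' @param records data.frame from [evaluate_records()], with a `fold` column.
#' @param group_keys character vector of grouping columns (e.g. `"model"`,
#'   `"intensity_pct_rmt"`).
#' @param metrics metric columns to aggregate.
#' @return A data.frame with one row per group x metric: `mean`, `sem_95`,
#'   `sem` (raw), `n_folds`, `degenerate`.
#' @export
aggregate_metrics <- function(records, group_keys = "model",
                              metrics = c("nrmse", "r2")) {
  stopifnot(all(c(group_keys, metrics, "fold") %in% names(records)))
  grp <- interaction(records[group_keys], drop = TRUE, sep = "|")
  out <- list()
  for (g in levels(grp)) {
    sub <- records[grp == g, , drop = FALSE]
    keyvals <- sub[1, group_keys, drop = FALSE]
    for (met in metrics) {
      ok <- !is.na(sub[[met]])
      fm <- tapply(sub[[met]][ok], sub$fold[ok], mean)
      nf <- length(fm)
      sem <- if (nf > 1) stats::sd(fm) / sqrt(nf) else 0
      row <- cbind(keyvals,
                   data.frame(metric = met, mean = mean(fm),
                              sem = sem, sem_95 = 1.96 * sem,
                              n_folds = nf, n_records = sum(ok),
                              degenerate = nf <= 1))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-intensity performance of a model
#'
#' Mean and 95\% SEM of NRMSE and R-squared for each stimulation intensity,
#' aggregated across folds: the intensity-stratified report.
#'
#' @param records data.frame from [evaluate_records()].
#' @return A data.frame keyed by `intensity_pct_rmt`.
#' @export
stratify_by_intensity <- function(records)
  aggregate_metrics(records, group_keys = "intensity_pct_rmt")

#' MEP response-profile analysis
#'
#' Relates reconstruction error to the richness of the muscle response:
#' returns the per-record table (`nrmse`, `mep_mean`, `mep_variance`,
#' `n_active`) plus box-plot summaries (median, quartiles) of NRMSE per
#' number of active muscles. Bins with no records are omitted.
#'
#' @param records data.frame from [evaluate_records()].
#' @return List with `records` and `by_n_active`.
#' @export
mep_profile_analysis <- function(records) {
  ok <- !is.na(records$nrmse)
  per <- records[ok, c("id", "nrmse", "mep_mean", "mep_variance", "n_active")]
  bins <- sort(unique(per$n_active))
  by_n <- do.call(rbind, lapply(bins, function(b) {
    v <- per$nrmse[per$n_active == b]
    data.frame(n_active = b, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))
  }))
  list(records = per, by_n_active = by_n)
}

#' Rank model variants
#'
#' Ranks variants by mean NRMSE (ascending), breaking ties by mean R-squared
#' (descending) and then by variant letter, and reports the pairwise
#' win/loss matrix on NRMSE.
#'
#' @param report aggregate report from [aggregate_metrics()] with a `model`
#'   key.
#' @return List with `ranking` (data.frame, best first) and `wins` (logical
#'   matrix: does the row variant beat the column variant?).
#' @export
compare_variants <- function(report) {
  nr <- report[report$metric == "nrmse", c("model", "mean")]
  r2 <- report[report$metric == "r2", c("model", "mean")]
  tab <- merge(nr, r2, by = "model", suffixes = c("_nrmse", "_r2"))
  tab$letter <- vapply(tab$model, variant_letter, character(1))
  ord <- order(tab$mean_nrmse, -tab$mean_r2, tab$letter)
  ranking <- tab[ord, c("model", "letter", "mean_nrmse", "mean_r2")]
  rownames(ranking) <- NULL
  wins <- outer(ranking$mean_nrmse, ranking$mean_nrmse, "<")
  dimnames(wins) <- list(ranking$model, ranking$model)
  list(ranking = ranking, wins = wins)
}
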