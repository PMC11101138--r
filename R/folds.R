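#' Intensity-stratified k-fold cross-validation splits
#'
#' Partitions the stimulation ids into k disjoint test folds such that the
#' per-intensity (%RMT) proportions of each fold match the full dataset
#' within one record per stratum, as required when pooling metrics across
#' folds. Deterministic given `seed`.
#'
#' @param dataset a [stim_dataset()] whose `coil$intensity_pct_rmt` labels
#'   the strata.
#' @param k number of folds.
#' @param seed integer seed controlling the within-stratum shuffle.
#' @return List of `k` fold splits, each a list with `fold_id` (0-based),
#'   `train_ids`, `test_ids`.
#' @export
stratified_kfold <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "stim_dataset"))
  ids <- dataset$coil$id
  strata <- dataset$coil$intensity_pct_rmt
  counts <- table(strata)
  short <- counts < k
  if (any(short))
    stop_mf("stratum %s has %d record(s), fewer than k = %d",
            names(counts)[short][1], counts[short][1], k)
  assign_fold <- integer(length(ids))
  with_seed(seed, {
    for (s in names(counts)) {
      idx <- which(strata == as.numeric(s))
      idx <- idx[sample.int(length(idx))]
      # round-robin keeps per-fold stratum counts within +/-1
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(fold_id = f - 1L,
         train_ids = ids[assign_fold != f],
         test_ids = ids[assign_fold == f])
  })
}

#' Subset a dataset by stimulation ids
#'
#' @param dataset a [stim_dataset()].
#' @param ids stimulation ids (matched against `coil$id`).
#' @return The dataset restricted to those records, in dataset order.
#' @export
subset_by_id <- function(dataset, ids) {
  keep <- dataset$coil$id %in% ids
  if (sum(keep) != length(unique(ids)))
    stop_mf("%d of %d requested ids not present", length(unique(ids)) - sum(keep),
            length(unique(ids)))
  subset_records(dataset, keep)
}
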