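#' Remove stimulations with no muscle response
#'
#' Stimulations whose MEP vector is identically zero carry no information for
#' the inverse mapping (they sit in the null space of the cortico-motor map)
#' and are removed before training. Order of the surviving records is
#' preserved and the number removed is recorded in `dataset$removed`.
#'
#' @param dataset a [stim_dataset()].
#' @return The filtered dataset.
#' @export
filter_zero_mep <- function(dataset) {
  stopifnot(inherits(dataset, "stim_dataset"))
  if (nrow(dataset$X) == 0L) stop_mf("empty dataset: no stimulations to filter")
  keep <- rowSums(dataset$meps != 0) > 0
  out <- subset_records(dataset, keep)
  out$removed["zero_mep"] <- out$removed["zero_mep"] + sum(!keep)
  out
}

#' Remove low E-field outlier stimulations
#'
#' Stimulations whose maximum masked E-field intensity falls strictly below
#' `threshold` (default 10 mV/m) are treated as experimental-error outliers
#' and removed. Applied on raw fields, before scaling: the threshold is
#' physical. Records exactly at the threshold are retained.
#'
#' @param dataset a [stim_dataset()] with raw (unscaled) E-fields.
#' @param threshold removal cutoff in V/m.
#' @return The filtered dataset.
#' @export
filter_low_efield <- function(dataset, threshold = 0.010) {
  stopifnot(inherits(dataset, "stim_dataset"))
  if (threshold <= 0) stop_mf("`threshold` must be positive, got %g", threshold)
  if (dataset$efield_scaled)
    stop_mf("E-fields already scaled; the %g V/m cutoff applies to raw fields",
            threshold)
  if (nrow(dataset$X) == 0L) stop_mf("empty dataset: no stimulations to filter")
  inside <- as.logical(dataset$mask$grid)
  maxima <- apply(dataset$X[, inside, drop = FALSE], 1L, max)
  keep <- maxima >= threshold
  out <- subset_records(dataset, keep)
  out$removed["low_efield"] <- out$removed["low_efield"] + sum(!keep)
  out
}

#' Min-max scale the E-field volumes
#'
#' The dataset-wide maximum masked voxel intensity is scaled to 1, voxels
#' outside the cortical mask are set to zero, and all other voxels scale
#' linearly, so the whole set of volumes lives in \[0, 1\] with exactly one
#' voxel attaining 1.
#'
#' @param dataset a [stim_dataset()] with raw E-fields.
#' @return List with `dataset` (scaled) and `scaling` ([scaling_params()]).
#' @export
scale_efields <- function(dataset) {
  stopifnot(inherits(dataset, "stim_dataset"))
  if (dataset$efield_scaled) stop_mf("E-fields are already scaled")
  inside <- as.logical(dataset$mask$grid)
  dataset$X[, !inside] <- 0
  gmax <- max(dataset$X)
  if (gmax <= 0)
    stop_mf("degenerate scaling: all masked E-field voxels are zero")
  dataset$X <- dataset$X / gmax
  dataset$efield_scaled <- TRUE
  sc <- dataset$scaling %||% scaling_params(muscles = dataset$muscles)
  sc$efield_global_max <- gmax
  dataset$scaling <- sc
  list(dataset = dataset, scaling = sc)
}

#' Min-max scale the MEP amplitudes
#'
#' Each muscle is scaled by its own dataset-wide maximum so every muscle that
#' is ever active attains 1 somewhere and all amplitudes lie in \[0, 1\]. A
#' muscle that is never active has an undefined divisor: its column is mapped
#' to zeros with a warning (the channel is kept so the network input width m
#' stays fixed).
#'
#' @param dataset a [stim_dataset()] with raw MEPs.
#' @return List with `dataset` (scaled) and `scaling` ([scaling_params()]).
#' @export
scale_meps <- function(dataset) {
  stopifnot(inherits(dataset, "stim_dataset"))
  if (dataset$mep_scaled) stop_mf("MEPs are already scaled")
  mx <- apply(dataset$meps, 2L, max)
  dead <- mx <= 0
  if (any(dead)) {
    warning(sprintf("muscle(s) never active, mapped to zeros: %s",
                    paste(dataset$muscles[dead], collapse = ", ")),
            call. = FALSE)
    mx[dead] <- 1 # divisor irrelevant: column is all zeros
  }
  dataset$meps <- sweep(dataset$meps, 2L, mx, "/")
  dataset$mep_scaled <- TRUE
  sc <- dataset$scaling %||% scaling_params(muscles = dataset$muscles)
  sc$mep_per_muscle_max <- stats::setNames(mx, dataset$muscles)
  dataset$scaling <- sc
  list(dataset = dataset, scaling = sc)
}

#' Invert the min-max scaling
#'
#' Restores raw physical units from a scaled dataset given its
#' [scaling_params()]; `unscale_dataset(scale(x))` recovers `x` to float
#' tolerance for all retained records.
#'
#' @param dataset a scaled [stim_dataset()].
#' @param scaling the [scaling_params()] produced when scaling.
#' @return The dataset in raw units.
#' @export
unscale_dataset <- function(dataset, scaling = dataset$scaling) {
  stopifnot(inherits(dataset, "stim_dataset"), inherits(scaling, "scaling_params"))
  if (dataset$efield_scaled) {
    dataset$X <- dataset$X * scaling$efield_global_max
    dataset$efield_scaled <- FALSE
  }
  if (dataset$mep_scaled) {
    dataset$meps <- sweep(dataset$meps, 2L, scaling$mep_per_muscle_max, "*")
    dataset$mep_scaled <- FALSE
  }
  dataset
}

#' Full preprocessing pipeline
#'
#' Zero-MEP removal, low E-field outlier removal (both on raw units), then
#' global E-field scaling and per-muscle MEP scaling.
#'
#' @param dataset a raw [stim_dataset()].
#' @param efield_threshold outlier cutoff in V/m.
#' @return List with `dataset` and `scaling`.
#' @export
preprocess_dataset <- function(dataset, efield_threshold = 0.010) {
  dataset <- filter_zero_mep(dataset)
  dataset <- filter_low_efield(dataset, efield_threshold)
  dataset <- scale_efields(dataset)$dataset
  res <- scale_meps(dataset)
  list(dataset = res$dataset, scaling = res$dataset$scaling)
}
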