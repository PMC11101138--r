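#' Stimulation dataset
#'
#' Aligned collection of TMS stimulations: per record a coil configuration,
#' the induced E-field volume, and the 15-muscle MEP response. Fields are
#' stored row-wise as an I x V matrix (V = prod(dim), column-major voxel
#' order) so the preprocessing and training code can operate on plain
#' matrices.
#'
#' @param X numeric matrix, one row per stimulation, one column per voxel.
#' @param dim integer 3-vector of volume dimensions.
#' @param meps numeric matrix of raw MEP amplitudes, one row per stimulation.
#' @param coil data.frame with columns `id`, `x`, `y`, `z` (mm),
#'   `orientation_deg`, `intensity_pct_rmt` and optionally `fringe`.
#' @param mask a [cortex_mask()] shared by all records.
#' @param voxel_size voxel edge in mm.
#' @param muscles muscle labels for the MEP columns.
#' @return An object of class `stim_dataset`.
#' @export
stim_dataset <- function(X, dim, meps, coil, mask, voxel_size = 1,
                         muscles = default_muscles(ncol(meps))) {
  stopifnot(is.matrix(X), is.matrix(meps), nrow(X) == nrow(meps),
            nrow(coil) == nrow(X), inherits(mask, "cortex_mask"))
  if (ncol(X) != prod(dim))
    stop_mf("X has %d voxel columns; dim [%s] implies %d",
            ncol(X), paste(dim, collapse = ","), prod(dim))
  colnames(meps) <- muscles
  structure(list(
    X = X, dim = as.integer(dim), voxel_size = voxel_size,
    meps = meps, muscles = muscles, coil = coil, mask = mask,
    efield_scaled = FALSE, mep_scaled = FALSE, scaling = NULL,
    removed = c(zero_mep = 0L, low_efield = 0L)
  ), class = "stim_dataset")
}

#' @export
print.stim_dataset <- function(x, ...) {
  cat(sprintf("<stim_dataset> %d stimulations, %s volume @ %g mm, %d muscles\n",
              nrow(x$X), paste(x$dim, collapse = "x"), x$voxel_size,
              ncol(x$meps)))
  cat(sprintf("  intensities: %s %%RMT\n",
              paste(sort(unique(x$coil$intensity_pct_rmt)), collapse = ", ")))
  cat(sprintf("  E-fields %s, MEPs %s\n",
              if (x$efield_scaled) "scaled" else "raw (V/m)",
              if (x$mep_scaled) "scaled" else "raw (uV)"))
  invisible(x)
}

#' @export
length.stim_dataset <- function(x) nrow(x$X)

#' Extract one stimulation record
#'
#' @param dataset a [stim_dataset()].
#' @param i row index.
#' @return List with `id`, `efield` ([efield_volume()]), `mep`
#'   ([mep_vector()]) and the coil parameters.
#' @export
get_record <- function(dataset, i) {
  stopifnot(inherits(dataset, "stim_dataset"))
  if (i < 1 || i > nrow(dataset$X)) stop_mf("record index %d out of range", i)
  list(
    id = dataset$coil$id[i],
    efield = efield_volume(array(dataset$X[i, ], dataset$dim),
                           dataset$voxel_size, dataset$efield_scaled),
    mep = mep_vector(dataset$meps[i, ], dataset$muscles),
    coil = dataset$coil[i, , drop = FALSE]
  )
}

subset_records <- function(dataset, keep) {
  dataset$X <- dataset$X[keep, , drop = FALSE]
  dataset$meps <- dataset$meps[keep, , drop = FALSE]
  dataset$coil <- dataset$coil[keep, , drop = FALSE]
  rownames(dataset$coil) <- NULL
  dataset
}

#' Dataset-wide min-max scaling constants
#'
#' The single global E-field divisor and the per-muscle MEP divisors derived
#' from one dataset, kept so that scaling is invertible and can be re-applied
#' to held-out data.
#'
#' @param efield_global_max maximum masked voxel intensity over the whole
#'   dataset (V/m).
#' @param mep_per_muscle_max per-muscle maximum amplitude (uV).
#' @param muscles muscle labels.
#' @return An object of class `scaling_params`.
#' @export
scaling_params <- function(efield_global_max = NULL, mep_per_muscle_max = NULL,
                           muscles = NULL) {
  structure(list(efield_global_max = efield_global_max,
                 mep_per_muscle_max = mep_per_muscle_max,
                 muscles = muscles),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("<scaling_params>\n")
  if (!is.null(x$efield_global_max))
    cat(sprintf("  E-field global max: %.5g V/m\n", x$efield_global_max))
  if (!is.null(x$mep_per_muscle_max))
    cat(sprintf("  MEP per-muscle max: %s uV\n",
                paste(signif(x$mep_per_muscle_max, 3), collapse = ", ")))
  invisible(x)
}
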