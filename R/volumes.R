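#' E-field volume
#'
#' A dense 3D grid of nonnegative electric-field intensities on the cortical
#' voxel lattice. Values are in V/m before min-max scaling and dimensionless
#' in \[0, 1\] afterwards.
#'
#' @param grid numeric 3D array of nonnegative intensities.
#' @param voxel_size edge length of a voxel in mm.
#' @param scaled logical; has dataset-wide min-max scaling been applied?
#' @return An object of class `efield_volume`.
#' @export
efield_volume <- function(grid, voxel_size = 1, scaled = FALSE) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop_mf("`grid` must be a 3D array, got dimensions [%s]",
            paste(dim(grid), collapse = ", "))
  if (any(grid < 0)) stop_mf("E-field intensities must be nonnegative")
  if (scaled && any(grid > 1 + 1e-9))
    stop_mf("scaled volume has values > 1")
  structure(list(grid = grid, voxel_size = voxel_size, scaled = scaled),
            class = "efield_volume")
}

#' @export
print.efield_volume <- function(x, ...) {
  cat(sprintf("<efield_volume> %s voxels @ %g mm, %s, max %.4g\n",
              paste(dim(x$grid), collapse = "x"), x$voxel_size,
              if (x$scaled) "scaled [0,1]" else "raw V/m", max(x$grid)))
  invisible(x)
}

#' Binary cortical mask
#'
#' Marks the motor-cortex voxels on which E-fields are nonzero; everything
#' outside is forced to zero ("masking"). Phantom masks also carry the
#' centreline and tangent field of the synthetic motor strip, used by the
#' field simulator's orientation sensitivity.
#'
#' @param grid binary (0/1 or logical) 3D array.
#' @return An object of class `cortex_mask`.
#' @export
cortex_mask <- function(grid) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop_mf("mask `grid` must be a 3D array")
  g <- grid != 0
  storage.mode(g) <- "integer"
  structure(list(grid = g), class = "cortex_mask")
}

#' @export
print.cortex_mask <- function(x, ...) {
  cat(sprintf("<cortex_mask> %s voxels, %.2f%% inside\n",
              paste(dim(x$grid), collapse = "x"),
              100 * mean(x$grid)))
  invisible(x)
}

#' Zero a volume outside a cortical mask
#'
#' Elementwise product of the intensity grid with the binary mask. Idempotent;
#' never increases a voxel value.
#'
#' @param volume an [efield_volume()].
#' @param mask a [cortex_mask()] of the same shape.
#' @return The masked `efield_volume`.
#' @export
apply_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "efield_volume"), inherits(mask, "cortex_mask"))
  if (!identical(dim(volume$grid), dim(mask$grid)))
    stop_mf("volume shape [%s] does not match mask shape [%s]",
            paste(dim(volume$grid), collapse = ","),
            paste(dim(mask$grid), collapse = ","))
  volume$grid <- volume$grid * mask$grid
  volume
}

#' MEP amplitude vector
#'
#' Peak-to-peak motor evoked potential amplitudes for the m recorded muscles
#' after one stimulation (microvolts raw, \[0, 1\] after per-muscle scaling).
#'
#' @param values nonnegative numeric vector of length m.
#' @param muscles character vector of muscle labels, same length.
#' @return A named numeric vector of class `mep_vector`.
#' @export
mep_vector <- function(values, muscles = default_muscles(length(values))) {
  if (length(values) != length(muscles))
    stop_mf("%d MEP values but %d muscle names", length(values), length(muscles))
  if (any(values < 0)) stop_mf("MEP amplitudes must be nonnegative")
  structure(stats::setNames(as.numeric(values), muscles), class = "mep_vector")
}

#' Default muscle panel
#'
#' The 15 hand and forearm muscles conventionally recorded in multi-muscle
#' TMS motor mapping.
#'
#' @param m number of muscles requested; the first `m` labels are returned
#'   (generic labels beyond 15).
#' @return Character vector of length `m`.
#' @export
default_muscles <- function(m = 15L) {
  base <- c("FDI", "3DI", "3Lum", "EI", "AbPB", "AdPB", "ADM", "FDM",
            "FCR", "FCU", "FDS", "EDC", "ECR", "ECU", "BRD")
  if (m <= length(base)) base[seq_len(m)]
  else c(base, sprintf("M%02d", seq.int(length(base) + 1L, m)))
}
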