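#' Read / write E-field volumes as NIfTI-1
#'
#' Volumes are stored as float32 NIfTI-1 with the voxel size on the diagonal
#' of the affine; the affine round-trips. `read_volume` accepts any NIfTI the
#' RNifti package can parse.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume an [efield_volume()].
#' @param scaled logical flag recorded on the returned volume.
#' @return `read_volume`: an `efield_volume`; `write_volume`: `path`,
#'   invisibly.
#' @export
read_volume <- function(path, scaled = FALSE) {
  if (!file.exists(path)) stop_mf("no such volume file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_mf("failed to parse NIfTI '%s': %s",
                                              path, conditionMessage(e)))
  grid <- array(as.numeric(img), dim(img)[1:3])
  vx <- RNifti::pixdim(img)[1]
  vol <- efield_volume(grid, voxel_size = vx, scaled = scaled)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  attr(vol, "affine") <- aff
  vol
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "efield_volume"))
  aff <- attr(volume, "affine")
  if (is.null(aff)) aff <- diag(c(rep(volume$voxel_size, 3), 1))
  g <- array(volume$grid, dim(volume$grid))
  attr(g, "pixdim") <- sqrt(colSums(aff[1:3, 1:3]^2))
  img <- RNifti::asNifti(g, datatype = "float")
  RNifti::sform(img) <- structure(aff, code = 2L) # full affine lives in sform
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write MEP tables as CSV
#'
#' Comma-separated, '.' decimal, UTF-8, with a mandatory header row naming
#' the muscles; one row per stimulation.
#'
#' @param path CSV file path.
#' @param meps numeric matrix (stimulations x muscles) with column names.
#' @return `read_mep_table`: list of [mep_vector()]s; `write_mep_table`:
#'   `path`, invisibly.
#' @export
read_mep_table <- function(path) {
  if (!file.exists(path)) stop_mf("no such MEP table: %s", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop_mf("failed to parse CSV '%s': %s",
                                             path, conditionMessage(e)))
  if (ncol(df) < 1L || is.null(names(df)))
    stop_mf("MEP table '%s' needs a header row of muscle names", path)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop_mf("non-numeric MEP entries in '%s'", path)
  lapply(seq_len(nrow(df)), function(i)
    mep_vector(as.numeric(df[i, ]), names(df)))
}

#' @rdname read_mep_table
#' @export
write_mep_table <- function(meps, path) {
  stopifnot(is.matrix(meps), !is.null(colnames(meps)))
  utils::write.csv(as.data.frame(meps), path, row.names = FALSE)
  invisible(path)
}

#' Write a dataset to disk
#'
#' One NIfTI volume per stimulation, a CSV MEP table, the mask volume, and a
#' JSON manifest with coil parameters, scaling constants and provenance.
#'
#' @param dataset a [stim_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "stim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset$X))) {
    rec <- get_record(dataset, i)
    write_volume(rec$efield,
                 file.path(dir, sprintf("efield_%04d.nii.gz", rec$id)))
  }
  write_mep_table(dataset$meps, file.path(dir, "meps.csv"))
  write_volume(efield_volume(array(as.numeric(dataset$mask$grid), dataset$dim),
                             dataset$voxel_size),
               file.path(dir, "mask.nii.gz"))
  manifest <- list(
    dim = dataset$dim, voxel_size = dataset$voxel_size,
    muscles = dataset$muscles, coil = dataset$coil,
    efield_scaled = dataset$efield_scaled, mep_scaled = dataset$mep_scaled,
    removed = as.list(dataset$removed),
    scaling = if (!is.null(dataset$scaling))
      list(efield_global_max = dataset$scaling$efield_global_max,
           mep_per_muscle_max = dataset$scaling$mep_per_muscle_max)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
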