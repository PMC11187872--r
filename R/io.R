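#' Load a 4D fMRI NIfTI volume with mask and TR
#'
#' Reads a NIfTI-1 file, attaches a brain mask (from `mask_path`, or by
#' default every voxel whose time course has nonzero variance), the
#' voxel-to-world affine, and the repetition time from the header's fourth
#' pixdim (overridable).
#'
#' @param path Path to a 4D `.nii`/`.nii.gz` file.
#' @param mask_path Optional path to a 3D mask on the same grid.
#' @param tr_override Repetition time in seconds; overrides the header.
#' @return An object of class `fmri_volume`: list with `data` (4D array),
#'   `mask` (3D logical), `affine` (4 x 4), `tr`.
#' @export
read_fmri <- function(path, mask_path = NULL, tr_override = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4) {
    abort("`path` must contain a 4D (x, y, z, time) volume.")
  }
  affine <- structure(RNifti::xform(img), class = "matrix")
  tr <- tr_override %||% RNifti::pixdim(img)[4]
  if (!is.numeric(tr) || length(tr) != 1 || !is.finite(tr) || tr <= 0) {
    abort("Repetition time must be positive; supply `tr_override`.")
  }
  sp <- dim(data)[1:3]
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (!identical(dim(mimg)[1:3], sp)) {
      abort("Mask grid does not match the data grid.")
    }
    mask <- array(as.numeric(mimg) != 0, dim = sp)
  } else {
    vm <- as_voxel_matrix(data)
    mask <- default_mask(vm$mat, sp)
  }
  structure(list(data = data, mask = mask, affine = unclass(affine), tr = tr),
            class = "fmri_volume")
}

#' Write an array as NIfTI-1
#'
#' @param data 3D or 4D numeric (or logical) array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param tr Repetition time in seconds, stored in pixdim 4 (4D data).
#' @param affine Optional 4 x 4 voxel-to-world matrix (default identity).
#' @return The path, invisibly.
#' @export
write_fmri <- function(data, path, tr = NULL, affine = NULL) {
  data <- array(as.numeric(data), dim = dim(data))
  img <- RNifti::asNifti(data)
  if (!is.null(affine)) {
    RNifti::qform(img) <- structure(affine, code = 2L)
  }
  if (!is.null(tr) && length(dim(data)) == 4) {
    pix <- RNifti::pixdim(img)
    pix[4] <- tr
    RNifti::pixdim(img) <- pix
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert MNI millimetre coordinates to voxel indices
#'
#' Applies the inverse of the NIfTI voxel-to-world affine and rounds to the
#' nearest voxel. The affine follows the NIfTI convention (0-based voxel
#' indices); the returned indices are 1-based for R array subsetting.
#'
#' @param coord_mm Numeric length-3 world (MNI) coordinate in mm.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param dim Optional grid dimensions; when given, out-of-grid results are
#'   an error.
#' @return Integer length-3 voxel index (1-based).
#' @export
mni_to_voxel <- function(coord_mm, affine, dim = NULL) {
  if (length(coord_mm) != 3) abort("`coord_mm` must have 3 components.")
  v0 <- solve(affine, c(as.numeric(coord_mm), 1))[1:3] # 0-based voxel
  v <- as.integer(round(v0)) + 1L
  if (!is.null(dim) && (any(v < 1L) || any(v > dim[1:3]))) {
    abort("Coordinate falls outside the image grid.")
  }
  v
}

#' Convert voxel indices to MNI millimetre coordinates
#'
#' @param voxel Integer length-3 voxel index (1-based).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return Numeric length-3 world coordinate in mm.
#' @export
voxel_to_mni <- function(voxel, affine) {
  if (length(voxel) != 3) abort("`voxel` must have 3 components.")
  as.numeric((affine %*% c(as.numeric(voxel) - 1, 1))[1:3])
}

#' Write a simulated dataset to disk
#'
#' Per subject: the noisy data and the noise-free data as NIfTI (the 2D
#' slice is stored as height x width x 1 x time), the subject's spatial
#' component maps as a 3D NIfTI (components along the third axis), and the
#' event trains and component time courses as one tidy CSV with columns
#' `time_index`, `component`, `event`, `amplitude`, `value`.
#'
#' @param dataset A [sim_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- dataset$config
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    d4 <- array(sub$data, dim = c(cfg$grid, 1L, cfg$n_time))
    write_fmri(d4, file.path(dir, sprintf("sub-%02d_bold.nii.gz", s)),
               tr = cfg$tr)
    write_fmri(sub$spatial,
               file.path(dir, sprintf("sub-%02d_components.nii.gz", s)))
    tc <- tidyr::expand_grid(component = seq_len(cfg$n_components),
                             time_index = seq_len(cfg$n_time)) |>
      dplyr::mutate(
        event = as.integer(dataset$subjects[[s]]$events[
          cbind(.data$time_index, .data$component)]),
        amplitude = dataset$subjects[[s]]$amplitudes[
          cbind(.data$time_index, .data$component)],
        value = dataset$subjects[[s]]$tc[
          cbind(.data$time_index, .data$component)]) |>
      dplyr::arrange(.data$time_index, .data$component)
    utils::write.csv(tc, file.path(dir, sprintf("sub-%02d_truth.csv", s)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Onset table for every mask voxel of a volume
#'
#' Runs [detect_onsets()] on each mask voxel's time course and returns one
#' row per detected onset — the tabular interface used by the command-line
#' `detect` tool.
#'
#' @param data Array with trailing time dimension.
#' @param mask Logical array over the spatial dimensions (default: nonzero
#'   variance).
#' @param ... Passed to [detect_onsets()].
#' @return Tibble with `voxel` (flat 1-based index), `onset` and `method`.
#' @export
detect_onsets_volume <- function(data, mask = NULL, ...) {
  vm <- as_voxel_matrix(data)
  if (is.null(mask)) mask <- default_mask(vm$mat, vm$dim)
  vox <- which(as.vector(mask))
  dots <- list(...)
  method <- dots$method %||% "zfr"
  purrr::map_dfr(vox, function(v) {
    on <- tryCatch(detect_onsets(vm$mat[v, ], ...),
                   error = function(e) integer())
    if (length(on) == 0) return(NULL)
    tibble::tibble(voxel = v, onset = on, method = method)
  })
}
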