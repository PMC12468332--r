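#' Write a volume image as NIfTI
#'
#' 2 mm isotropic lattice; the affine records the scanner coordinate
#' convention (x/y across the ring, z vertical with 0 at the table plane and
#' negative downwards, voxel centres as in the grid).
#'
#' @param volume a `volume_image` (or plain 3D array with `grid`).
#' @param path output `.nii` / `.nii.gz` path.
#' @param grid a [voxel_grid()] (taken from the volume when missing).
#' @export
write_volume_nifti <- function(volume, path, grid = NULL) {
  data <- if (inherits(volume, "volume_image")) volume$data else volume
  if (is.null(grid)) grid <- volume$grid
  dz <- if (length(grid$z) > 1) grid$z[2] - grid$z[1] else grid$spacing
  aff <- rbind(c(grid$spacing, 0, 0, grid$x[1]),
               c(0, grid$spacing, 0, grid$y[1]),
               c(0, 0, dz, grid$z[1]),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a `volume_image`
#'
#' Accepts externally supplied volumes for the analysis back half of the
#' chain; the breast mask defaults to the positive-intensity support.
#'
#' @param path NIfTI path.
#' @param mask optional logical mask array.
#' @export
read_volume_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  aff <- RNifti::xform(img)
  sp <- abs(aff[1, 1])
  grid <- list(x = aff[1, 4] + (seq_len(dim(data)[1]) - 1) * aff[1, 1],
               y = aff[2, 4] + (seq_len(dim(data)[2]) - 1) * aff[2, 2],
               z = aff[3, 4] + (seq_len(dim(data)[3]) - 1) * aff[3, 3],
               spacing = sp)
  if (is.null(mask)) mask <- data > 0
  structure(list(data = data, grid = grid, mask = mask,
                 cutout = NA_integer_,
                 excluded = rep(FALSE, dim(data)[3]),
                 provenance = basename(path)),
            class = "volume_image")
}

#' Persist / load scan data
#'
#' Self-describing container (complex tensor, geometry, frequency grid,
#' seed). The loader validates the structure and the absent monostatic
#' diagonal.
#'
#' @param scan a `scan_data` object.
#' @param path file path.
#' @export
save_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_data"))
  saveRDS(scan, path)
  invisible(path)
}

#' @rdname save_scan
#' @export
load_scan <- function(path) {
  scan <- readRDS(path)
  if (!inherits(scan, "scan_data")) stop("not a scan_data container")
  np <- dim(scan$s21)[1]
  diag_ok <- all(is.na(scan$s21[cbind(rep(seq_len(np), 2)[seq_len(np)],
                                      seq_len(np), 1, 1)]))
  if (!diag_ok) stop("container failed validation: monostatic diagonal present")
  scan
}

#' Write / read a run configuration
#'
#' Structured key-value (YAML) serialization of a [run_config()].
#'
#' @param config a [run_config()] list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
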