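#' Stack of gray-matter images on a shared grid
#'
#' A `gm_volume_set` holds one modulated gray-matter image per subject as a
#' subjects x voxels matrix, together with the grid geometry. Row order is
#' the single source of truth for subject alignment across every module:
#' rows always match the cohort table they were generated from.
#'
#' @param data numeric matrix, subjects x voxels, voxels in column-major
#'   (array) order; values must be nonnegative.
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param subject_ids character subject identifiers (row names).
#' @return object of class `gm_volume_set`.
#' @export
gm_volume_set <- function(data, grid_shape, voxel_size, subject_ids = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(is.matrix(data), length(grid_shape) == 3L,
            ncol(data) == prod(grid_shape), voxel_size > 0)
  if (any(data < 0)) stop("gray-matter values must be nonnegative")
  if (!is.null(subject_ids)) {
    stopifnot(length(subject_ids) == nrow(data))
    rownames(data) <- subject_ids
  }
  structure(list(data = data, grid_shape = grid_shape,
                 voxel_size = voxel_size),
            class = "gm_volume_set")
}

#' @export
print.gm_volume_set <- function(x, ...) {
  cat(sprintf("GM volume set: %d subjects on %s grid (%.1f mm voxels)\n",
              nrow(x$data), paste(x$grid_shape, collapse = "x"), x$voxel_size))
  invisible(x)
}

#' @export
dim.gm_volume_set <- function(x) dim(x$data)

#' Subset a volume set by subject
#' @param x a `gm_volume_set`.
#' @param i subject index vector.
#' @param ... unused.
#' @return a `gm_volume_set` with the selected rows.
#' @export
`[.gm_volume_set` <- function(x, i, ...) {
  gm_volume_set(x$data[i, , drop = FALSE], x$grid_shape, x$voxel_size)
}

#' Write / read a volume set as a 4-D NIfTI stack
#'
#' @param set a `gm_volume_set`.
#' @param path NIfTI file path.
#' @return `read_volume_set` returns a `gm_volume_set`.
#' @export
write_volume_set <- function(set, path) {
  arr <- array(t(set$data), dim = c(set$grid_shape, nrow(set$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(set$voxel_size, 3), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_set
#' @export
read_volume_set <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  data <- t(matrix(img, nrow = prod(d[1:3]), ncol = d[4]))
  gm_volume_set(data, d[1:3], RNifti::pixdim(img)[1])
}
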