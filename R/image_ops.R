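#' Total tissue volume per subject
#'
#' Integrates each subject's tissue map over all voxels and multiplies by the
#' voxel volume, reporting the result in mL (1 mL = 1000 mm^3). Totals are
#' computed from unsmoothed images in the pipeline, matching the convention
#' that global tissue volumes come from native-resolution segmentations.
#'
#' @param images a `gm_volume_set`, or a subjects x voxels matrix.
#' @param voxel_size voxel edge length in mm (ignored when `images` is a
#'   `gm_volume_set`, which carries its own).
#' @return numeric vector, one total volume in mL per subject.
#' @export
#' @examples
#' set <- gm_volume_set(matrix(1, 2, 8), c(2, 2, 2), voxel_size = 1.5)
#' compute_tissue_totals(set)  # 8 voxels x 3.375 mm^3 = 0.027 mL each
compute_tissue_totals <- function(images, voxel_size = NULL) {
  if (inherits(images, "gm_volume_set")) {
    voxel_size <- images$voxel_size
    images <- images$data
  }
  stopifnot(is.matrix(images), !is.null(voxel_size), voxel_size > 0)
  if (any(images < 0)) stop("tissue maps must be nonnegative")
  rowSums(images) * voxel_size^3 / 1000
}

#' Total intracranial volume
#'
#' TIV is the sum of the three major tissue-class totals.
#'
#' @param tgm,twm,tcsf total gray matter, white matter and CSF volumes (mL).
#' @return TIV in mL.
#' @export
compute_tiv <- function(tgm, twm, tcsf) {
  if (missing(tgm) || missing(twm) || missing(tcsf))
    stop("all three tissue-class totals (tgm, twm, tcsf) are required")
  stopifnot(all(tgm >= 0), all(twm >= 0), all(tcsf >= 0))
  tgm + twm + tcsf
}

# 1-D smoothing operator with mirror (reflect) boundary handling. Because all
# kernel mass reflected at an edge lands back inside the domain, every column
# sums to 1 and smoothing preserves the image total exactly.
smoothing_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox == 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    # half-sample mirror: reflect about the domain edges; this extension
    # repeats every sample exactly twice per period, so folding the kernel
    # back preserves column sums (and hence image totals) exactly
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    for (t in seq_along(j)) S[i, j[t]] <- S[i, j[t]] + k[t]
  }
  S
}

#' Isotropic Gaussian smoothing of a volume set
#'
#' Applies a separable Gaussian filter with the stated full width at half
#' maximum, using `sigma = fwhm / (2 sqrt(2 ln 2)) / voxel_size` voxels per
#' axis. Boundary handling is mirror (reflect) padding, which preserves each
#' image's total exactly. `fwhm = 0` is the identity.
#'
#' @param images a `gm_volume_set`.
#' @param fwhm_mm kernel full width at half maximum in mm (default 8).
#' @return a smoothed `gm_volume_set`.
#' @export
gaussian_smooth <- function(images, fwhm_mm = 8) {
  stopifnot(inherits(images, "gm_volume_set"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("'fwhm_mm' must be a single nonnegative number")
  if (fwhm_mm == 0) return(images)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / images$voxel_size
  g <- images$grid_shape
  S <- lapply(g, smoothing_matrix_1d, sigma_vox = sigma)
  n <- nrow(images$data)
  # one 4-D array (x, y, z, subject); each separable pass is a single matrix
  # product with the smoothing axis brought to the front
  a <- array(t(images$data), dim = c(g, n))
  a <- array(S[[1]] %*% matrix(a, g[1]), dim = c(g, n))
  a <- aperm(array(S[[2]] %*% matrix(aperm(a, c(2, 1, 3, 4)), g[2]),
                   dim = c(g[2], g[1], g[3], n)), c(2, 1, 3, 4))
  a <- aperm(array(S[[3]] %*% matrix(aperm(a, c(3, 1, 2, 4)), g[3]),
                   dim = c(g[3], g[1], g[2], n)), c(2, 3, 1, 4))
  out <- t(matrix(a, prod(g), n))
  gm_volume_set(pmax(out, 0), g, images$voxel_size, rownames(images$data))
}

#' Analysis mask from the mean smoothed image
#'
#' The mask is the set of voxels whose across-subject mean (of the smoothed,
#' normalized gray-matter images) exceeds the threshold. The same mask is
#' used for every statistical model so that adjustment modes are compared on
#' identical voxels.
#'
#' @param smoothed_set a `gm_volume_set` of smoothed images.
#' @param threshold mean-GM threshold (default 0.1, in modulated GM density
#'   units).
#' @return object of class `brain_mask`: list with logical vector `mask`,
#'   `grid_shape`, `voxel_size`, `n_voxels`.
#' @export
make_mask <- function(smoothed_set, threshold = 0.1) {
  stopifnot(inherits(smoothed_set, "gm_volume_set"), nrow(smoothed_set$data) > 0)
  mean_img <- colMeans(smoothed_set$data)
  mask <- mean_img > threshold
  if (!any(mask))
    stop(sprintf(paste0("mask is empty at threshold %g (max mean GM %.4g); ",
                        "lower the threshold"), threshold, max(mean_img)))
  structure(list(mask = mask, grid_shape = smoothed_set$grid_shape,
                 voxel_size = smoothed_set$voxel_size,
                 n_voxels = sum(mask)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("Brain mask: %d of %d voxels in-mask\n", x$n_voxels,
              prod(x$grid_shape)))
  invisible(x)
}

#' Write a binary mask as uint8 NIfTI
#' @param mask a `brain_mask`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  arr <- array(as.integer(mask$mask), dim = mask$grid_shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(mask$voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
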