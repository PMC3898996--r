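#' Build a synthetic bilateral atlas
#'
#' Constructs an integer-labelled parcellation on a small analysis grid that
#' mimics the cardinality of the AAL atlas: 116 regions by default, 58 per
#' hemisphere, with homologous left/right pairs mirrored about the midline of
#' the first (x) axis. Regions are cubic blocks of `block` voxels per side,
#' spread deterministically over each hemisphere; unassigned blocks remain
#' background (label 0). Labels follow the AAL convention of alternating
#' left/right homologues: region pair k gets labels 2k-1 (L) and 2k (R).
#'
#' This is a *synthetic* stand-in for an anatomical atlas: it reproduces the
#' label structure (integer image + label table with names and hemispheres)
#' that ROI analyses consume, not any anatomy.
#'
#' @param grid_shape integer length-3 grid dimensions in voxels; the first
#'   axis is split at its midpoint into left/right hemispheres, so it must be
#'   even.
#' @param block region block side length in voxels; must divide every grid
#'   dimension.
#' @param n_per_hemisphere number of regions per hemisphere (default 58).
#' @param voxel_size isotropic voxel size in mm.
#' @return object of class `gm_atlas`: list with `labels` (integer 3-D
#'   array), `table` (data.frame: `label`, `name`, `hemisphere`), `grid_shape`,
#'   `voxel_size`.
#' @export
#' @examples
#' atl <- synthetic_atlas(grid_shape = c(12, 12, 12), block = 4,
#'                        n_per_hemisphere = 6)
#' nrow(atl$table)
synthetic_atlas <- function(grid_shape = c(24, 24, 24), block = 4,
                            n_per_hemisphere = 58, voxel_size = 1.5) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  if (grid_shape[1] %% 2L != 0L)
    stop("first grid dimension must be even (hemisphere split)")
  if (any(grid_shape %% block != 0L))
    stop("'block' must divide every grid dimension")
  nb <- grid_shape %/% block
  half_x <- nb[1] %/% 2L
  n_blocks_hemi <- half_x * nb[2] * nb[3]
  if (n_per_hemisphere > n_blocks_hemi)
    stop(sprintf("grid holds only %d blocks per hemisphere, %d requested",
                 n_blocks_hemi, n_per_hemisphere))

  # deterministic, evenly spread block selection within the left hemisphere
  sel <- unique(round(seq(1, n_blocks_hemi, length.out = n_per_hemisphere)))
  stopifnot(length(sel) == n_per_hemisphere)

  labels <- array(0L, grid_shape)
  blk_index <- function(bx, by, bz) ((bz - 1L) * nb[2] + (by - 1L)) * half_x + bx
  for (bz in seq_len(nb[3])) for (by in seq_len(nb[2])) for (bx in seq_len(half_x)) {
    k <- match(blk_index(bx, by, bz), sel)
    if (is.na(k)) next
    xs <- ((bx - 1L) * block + 1L):(bx * block)
    ys <- ((by - 1L) * block + 1L):(by * block)
    zs <- ((bz - 1L) * block + 1L):(bz * block)
    labels[xs, ys, zs] <- 2L * k - 1L                      # left
    labels[grid_shape[1] + 1L - xs, ys, zs] <- 2L * k      # mirrored right
  }

  tab <- data.frame(
    label = seq_len(2L * n_per_hemisphere),
    name = sprintf("Region_%03d_%s", rep(seq_len(n_per_hemisphere), each = 2),
                   rep(c("L", "R"), n_per_hemisphere)),
    hemisphere = rep(c("L", "R"), n_per_hemisphere),
    stringsAsFactors = FALSE
  )
  structure(list(labels = labels, table = tab, grid_shape = grid_shape,
                 voxel_size = voxel_size),
            class = "gm_atlas")
}

#' @export
print.gm_atlas <- function(x, ...) {
  cat(sprintf("Synthetic atlas: %d regions (%d L / %d R) on %s grid, %.1f mm voxels\n",
              nrow(x$table), sum(x$table$hemisphere == "L"),
              sum(x$table$hemisphere == "R"),
              paste(x$grid_shape, collapse = "x"), x$voxel_size))
  invisible(x)
}

#' Default per-region generative coefficients
#'
#' Draws one generative parameter set per atlas region for the gray-matter
#' image simulator. The defaults encode what a structural-aging dataset looks
#' like after modulated VBM preprocessing:
#'
#' * mean modulated GM density `m_r` ~ U(0.4, 0.8) (unitless);
#' * linear age slope `b_r = -rate_r * m_r`, with the fractional annual
#'   decline `rate_r` ~ U(0.02%, 0.25%) per year, so regions lose between
#'   ~1% and ~15% of their mean GM over a six-decade span and faster-declining
#'   regions are spread independently of their size;
#' * a small negative quadratic term `q_r` (decline accelerates late in life);
#' * head-size coupling `h_r` proportional to `m_r` (bigger heads, more GM);
#' * global-factor loading `lambda_r`: with `coupling = "proportional"` every
#'   region loads on the shared individual factor in proportion to its mean
#'   (the regime in which Global Scaling is the correct adjustment); with
#'   `coupling = "heterogeneous"` loadings are drawn independently of region
#'   means (the regime in which Local Covariation is correct).
#'
#' @param atlas a [synthetic_atlas()].
#' @param coupling `"proportional"` or `"heterogeneous"` global-factor
#'   loading structure.
#' @param seed integer seed.
#' @return data.frame of class `region_specs` with one row per region:
#'   `label`, `hemisphere`, `mean_gm`, `linear_slope`, `quad_slope`,
#'   `tiv_coef`, `global_coef`.
#' @export
region_specs_default <- function(atlas,
                                 coupling = c("proportional", "heterogeneous"),
                                 seed = 1L) {
  coupling <- match.arg(coupling)
  stopifnot(inherits(atlas, "gm_atlas"))
  set.seed(seed)
  n <- nrow(atlas$table)
  m <- stats::runif(n, 0.4, 0.8)
  rate <- stats::runif(n, 2e-4, 2.5e-3)       # fractional decline per year
  lambda <- switch(coupling,
                   proportional  = 0.05 * m,
                   heterogeneous = stats::runif(n, 0.005, 0.08))
  specs <- data.frame(
    label = atlas$table$label,
    hemisphere = atlas$table$hemisphere,
    mean_gm = m,
    linear_slope = -rate * m,
    quad_slope = -m * stats::runif(n, 0, 2e-5),
    tiv_coef = 3e-4 * m,
    global_coef = lambda,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(specs$label)) stop_config("label", "must be unique")
  class(specs) <- c("region_specs", "data.frame")
  attr(specs, "coupling") <- coupling
  specs
}

#' Write / read an atlas as NIfTI plus a label TSV
#'
#' @param atlas a `gm_atlas`.
#' @param image_path NIfTI path for the integer label image.
#' @param table_path TSV path for the label table.
#' @return `read_atlas` returns a `gm_atlas`.
#' @export
write_atlas <- function(atlas, image_path, table_path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- rep(atlas$voxel_size, 3)
  RNifti::writeNifti(img, image_path)
  utils::write.table(atlas$table, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(image_path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(image_path, table_path) {
  img <- RNifti::readNifti(image_path)
  labels <- array(as.integer(round(img)), dim = dim(img))
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  structure(list(labels = labels, table = tab,
                 grid_shape = dim(labels),
                 voxel_size = RNifti::pixdim(img)[1]),
            class = "gm_atlas")
}
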