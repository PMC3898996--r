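#' Specify gray-matter image generation
#'
#' Controls the voxel-level generative model used by [generate_gm_images()]
#' and [generate_proportional_dataset()].
#'
#' @param grid_shape integer length-3 voxel grid (default 24^3).
#' @param voxel_size isotropic voxel size in mm (default 1.5).
#' @param pv_profile `"uniform"` or `"radial"` within-region partial-volume
#'   profile. The radial profile decreases linearly with normalized distance
#'   from the region centroid (1 at the centre, `pv_floor` at the edge),
#'   emulating the attenuation of tissue density towards region boundaries
#'   that couples a voxel's mean GM to the magnitude of its age effect.
#' @param pv_floor partial-volume weight at the region edge, in (0, 1].
#' @param noise_sd voxel-level Gaussian noise SD in modulated GM density
#'   units (default 0.05).
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm for the smoothed
#'   output set (default 8; 0 skips smoothing).
#' @param seed integer seed.
#' @return object of class `image_gen_spec`.
#' @export
image_gen_spec <- function(grid_shape = c(24, 24, 24), voxel_size = 1.5,
                           pv_profile = c("radial", "uniform"),
                           pv_floor = 0.5, noise_sd = 0.05,
                           smoothing_fwhm = 8, seed = 1L) {
  pv_profile <- match.arg(pv_profile)
  if (any(grid_shape <= 0)) stop_config("grid_shape", "must be positive")
  if (voxel_size <= 0) stop_config("voxel_size", "must be > 0")
  if (pv_floor <= 0 || pv_floor > 1) stop_config("pv_floor", "must lie in (0, 1]")
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (smoothing_fwhm < 0) stop_config("smoothing_fwhm", "must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 pv_profile = pv_profile, pv_floor = pv_floor,
                 noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
                 seed = as.integer(seed)),
            class = "image_gen_spec")
}

# Per-voxel partial-volume weights for an atlas under a generation spec.
# Radial: p_v = floor + (1 - floor) * (1 - d/dmax), linear in normalized
# Euclidean distance from the region centroid; single-voxel regions get 1.
partial_volume_weights <- function(atlas, spec) {
  g <- atlas$grid_shape
  lab <- as.integer(atlas$labels)
  p <- numeric(prod(g))
  p[lab > 0] <- 1
  if (spec$pv_profile == "radial") {
    coords <- cbind(
      rep(seq_len(g[1]), times = g[2] * g[3]),
      rep(rep(seq_len(g[2]), each = g[1]), times = g[3]),
      rep(seq_len(g[3]), each = g[1] * g[2])
    )
    for (l in atlas$table$label) {
      idx <- which(lab == l)
      if (!length(idx)) next
      ctr <- colMeans(coords[idx, , drop = FALSE])
      d <- sqrt(rowSums((coords[idx, , drop = FALSE] -
                           matrix(ctr, length(idx), 3, byrow = TRUE))^2))
      dmax <- max(d)
      p[idx] <- if (dmax > 0)
        spec$pv_floor + (1 - spec$pv_floor) * (1 - d / dmax) else 1
    }
  }
  p
}

#' Generate modulated gray-matter image stacks
#'
#' Simulates, for each subject, the *output* of a modulated VBM preprocessing
#' chain: a normalized gray-matter density image in which a voxel `v` of
#' region `r` takes the value
#'
#' `y_iv = p_v * [m_r + b_r (a_i - abar) + q_r (a_i - abar)^2 +
#'         h_r (TIV_i - TIVbar) + lambda_r g_i] + eps_iv`
#'
#' clipped at zero, where `p_v` is the within-region partial-volume weight,
#' `g_i ~ N(0, 1)` is a global individual factor shared by every region, and
#' `eps_iv ~ N(0, noise_sd^2)`. Age and TIV are centered at the cohort means
#' inside the generator, so `m_r` is the cohort-mean voxel GM of a
#' full-volume voxel. Voxels outside the atlas are exactly zero (synthetic
#' "air"), so the integral of an unsmoothed image equals the subject's TGM.
#'
#' The returned cohort has its `tgm` column filled from the generated
#' unsmoothed images via [compute_tissue_totals()]; `twm` and `tcsf` are set
#' so that `tiv = tgm + twm + tcsf` holds by construction.
#'
#' @param cohort a `gm_cohort`.
#' @param regions a `region_specs` data frame covering every atlas label.
#' @param atlas a `gm_atlas`.
#' @param spec an [image_gen_spec()].
#' @return list with `unsmoothed` and `smoothed` (`gm_volume_set`s; `smoothed`
#'   is `NULL` when `smoothing_fwhm = 0`), `cohort` (tissue totals filled
#'   in), and `ground_truth` (realized coefficients, per-subject global
#'   factors `g`, per-voxel weights `p_v`, clipping rate, centering means).
#' @export
generate_gm_images <- function(cohort, regions, atlas, spec = image_gen_spec()) {
  stopifnot(inherits(atlas, "gm_atlas"), nrow(cohort) > 0)
  lab <- as.integer(atlas$labels)
  present <- sort(unique(lab[lab > 0]))
  missing <- setdiff(present, regions$label)
  if (length(missing))
    stop("atlas labels without a region specification: ",
         paste(missing, collapse = ", "))

  set.seed(spec$seed)
  n <- nrow(cohort)
  p_v <- partial_volume_weights(atlas, spec)
  g_i <- stats::rnorm(n)

  a_c <- cohort$age - mean(cohort$age)
  tiv_c <- cohort$tiv - mean(cohort$tiv)

  # per-voxel coefficient rows: columns of (1, a_c, a_c^2, tiv_c, g)
  ridx <- match(lab, regions$label)          # NA outside atlas
  coefs <- rbind(regions$mean_gm, regions$linear_slope, regions$quad_slope,
                 regions$tiv_coef, regions$global_coef)
  V <- length(lab)
  C <- matrix(0, 5, V)
  C[, !is.na(ridx)] <- coefs[, ridx[!is.na(ridx)]]
  C <- C * rep(p_v, each = 5)

  design <- cbind(1, a_c, a_c^2, tiv_c, g_i)
  Y <- design %*% C
  if (spec$noise_sd > 0) {
    in_atlas <- which(!is.na(ridx))
    Y[, in_atlas] <- Y[, in_atlas] +
      stats::rnorm(n * length(in_atlas), sd = spec$noise_sd)
  }
  clipped <- Y < 0
  clip_rate <- mean(clipped[, !is.na(ridx), drop = FALSE])
  if (clip_rate > 0.01)
    warning(sprintf("%.2f%% of in-atlas voxel values clipped at 0", 100 * clip_rate))
  Y[clipped] <- 0

  unsmoothed <- gm_volume_set(Y, spec$grid_shape, spec$voxel_size,
                              cohort$subject_id)
  smoothed <- if (spec$smoothing_fwhm > 0)
    gaussian_smooth(unsmoothed, spec$smoothing_fwhm) else NULL

  cohort$tgm <- unname(compute_tissue_totals(unsmoothed))
  rem <- pmax(cohort$tiv - cohort$tgm, 0)
  cohort$twm <- 0.6 * rem
  cohort$tcsf <- 0.4 * rem

  ground_truth <- list(regions = regions, g = g_i, p_v = p_v,
                       clip_rate = clip_rate,
                       age_mean = mean(cohort$age),
                       tiv_mean = mean(cohort$tiv),
                       region_index = ridx)
  list(unsmoothed = unsmoothed, smoothed = smoothed, cohort = cohort,
       ground_truth = ground_truth)
}

#' Generate a purely proportional dataset
#'
#' Null model for Global Scaling: every voxel is proportional to a
#' per-subject global level `G_i = G(a_i) u_i`, where `G(a)` declines
#' linearly with age and `u_i` is multiplicative log-normal noise, plus
#' independent voxel noise:
#'
#' `y_iv = p_v m_r G_i + eps_iv`
#'
#' After dividing by TGM, all systematic age dependence is removed, so any
#' adjustment that assumes proportional global effects should find no
#' regional age effect in these data.
#'
#' @param cohort a `gm_cohort`.
#' @param regions a `region_specs` data frame.
#' @param atlas a `gm_atlas`.
#' @param spec an [image_gen_spec()].
#' @param decline_per_year fractional decline of `G(a)` per year of age
#'   (default 0.001, i.e. ~6% over a six-decade span).
#' @param subject_noise_sd SD of `log(u_i)` (default 0.05).
#' @return as [generate_gm_images()]; the ground truth records `G_i`.
#' @export
generate_proportional_dataset <- function(cohort, regions, atlas,
                                          spec = image_gen_spec(),
                                          decline_per_year = 0.001,
                                          subject_noise_sd = 0.05) {
  stopifnot(inherits(atlas, "gm_atlas"), nrow(cohort) > 0)
  lab <- as.integer(atlas$labels)
  present <- sort(unique(lab[lab > 0]))
  missing <- setdiff(present, regions$label)
  if (length(missing))
    stop("atlas labels without a region specification: ",
         paste(missing, collapse = ", "))

  set.seed(spec$seed)
  n <- nrow(cohort)
  p_v <- partial_volume_weights(atlas, spec)
  u <- exp(stats::rnorm(n, sd = subject_noise_sd))
  G <- (1 - decline_per_year * (cohort$age - min(cohort$age))) * u

  ridx <- match(lab, regions$label)
  mv <- numeric(length(lab))
  mv[!is.na(ridx)] <- regions$mean_gm[ridx[!is.na(ridx)]]
  mv <- mv * p_v

  Y <- outer(G, mv)
  if (spec$noise_sd > 0) {
    in_atlas <- which(!is.na(ridx))
    Y[, in_atlas] <- Y[, in_atlas] +
      stats::rnorm(n * length(in_atlas), sd = spec$noise_sd)
  }
  Y[Y < 0] <- 0

  unsmoothed <- gm_volume_set(Y, spec$grid_shape, spec$voxel_size,
                              cohort$subject_id)
  smoothed <- if (spec$smoothing_fwhm > 0)
    gaussian_smooth(unsmoothed, spec$smoothing_fwhm) else NULL

  cohort$tgm <- unname(compute_tissue_totals(unsmoothed))
  rem <- pmax(cohort$tiv - cohort$tgm, 0)
  cohort$twm <- 0.6 * rem
  cohort$tcsf <- 0.4 * rem

  list(unsmoothed = unsmoothed, smoothed = smoothed, cohort = cohort,
       ground_truth = list(regions = regions, G = G, p_v = p_v,
                           region_index = ridx))
}

#' Generate the two-region toy dataset
#'
#' A minimal illustration of how the four global-adjustment strategies can
#' lead to different conclusions from identical data: six subjects (two at
#' each of three ages), two regions whose gray matter declines linearly with
#' age, Region 1 twice as fast as Region 2, slopes proportional to the
#' region means, plus a shared per-subject global deviation and small
#' independent noise. Total gray matter is the sum of the two regions.
#'
#' Because the slopes are proportional to the means, Global Scaling removes
#' the age effect in both regions and Local Scaling equalizes the two scaled
#' slopes; because the global deviation loads equally on both regions, Local
#' Covariation flips the slower region's slope positive. The global
#' deviation is drawn from the seed and then orthogonalized to age and
#' recentred, so the toy's age effects are not confounded with the
#' particular global draw at this tiny sample size.
#'
#' @param ages subject ages (default two subjects at each of 30, 60, 90).
#' @param mean_gm length-2 region mean GM (arbitrary GMV units).
#' @param decline_frac shared fractional decline per year; region slopes are
#'   `-decline_frac * mean_gm`.
#' @param global_sd SD of the shared per-subject global deviation.
#' @param noise_sd SD of independent per-observation noise.
#' @param seed integer seed.
#' @return 6-row data.frame: `subject`, `age`, `region1_gm`, `region2_gm`,
#'   `tgm`, with the generative parameters attached as attributes.
#' @export
generate_fig1_dataset <- function(ages = c(30, 30, 60, 60, 90, 90),
                                  mean_gm = c(4, 2),
                                  decline_frac = 0.005,
                                  global_sd = 0.08,
                                  noise_sd = 0.03,
                                  seed = 11L) {
  stopifnot(length(mean_gm) == 2L, all(mean_gm > 0), decline_frac > 0,
            global_sd >= 0, noise_sd >= 0, length(ages) >= 4L)
  set.seed(seed)
  n <- length(ages)
  a_c <- ages - mean(ages)
  g <- stats::rnorm(n)
  # orthogonalize the global deviation to [1, age] and fix its scale
  g <- stats::residuals(stats::lm.fit(cbind(1, a_c), g))
  g <- g / stats::sd(g) * global_sd
  slope <- -decline_frac * mean_gm
  y1 <- mean_gm[1] + slope[1] * a_c + g + stats::rnorm(n, sd = noise_sd)
  y2 <- mean_gm[2] + slope[2] * a_c + g + stats::rnorm(n, sd = noise_sd)
  out <- data.frame(subject = sprintf("s%d", seq_len(n)), age = ages,
                    region1_gm = y1, region2_gm = y2, tgm = y1 + y2)
  attr(out, "params") <- list(mean_gm = mean_gm, slope = slope,
                              decline_frac = decline_frac,
                              global_sd = global_sd, noise_sd = noise_sd,
                              seed = seed)
  out
}
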