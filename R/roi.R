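#' Reconstruct a full-grid map from a masked voxelwise fit
#'
#' @param fit a `vbm_fit` on voxel data (unit ids are in-grid voxel
#'   indices).
#' @param what `"slope"` (sex-averaged linear age effect), `"lgm"`,
#'   `"t"`, `"p"` or `"scaled_slope"`.
#' @return numeric vector over the full grid, `NA` outside the fitted units.
#' @export
map_from_fit <- function(fit, what = c("slope", "lgm", "t", "p", "scaled_slope")) {
  what <- match.arg(what)
  stopifnot(!is.null(fit$mask))
  vals <- switch(what,
                 slope = fit$contrast$effect,
                 lgm = fit$lgm,
                 t = fit$contrast$t,
                 p = fit$contrast$p,
                 scaled_slope = {
                   if (is.null(fit$scaling))
                     stop("fit has no local-scaling map; use adjustment = 'local_scaling'")
                   fit$scaling$scaled_slope
                 })
  out <- rep(NA_real_, prod(fit$mask$grid_shape))
  out[fit$unit_ids] <- vals
  out
}

#' Average an effect map within atlas regions
#'
#' Mean of the in-mask voxel values for every atlas label. Labels with no
#' in-mask voxel are reported as `NA` with a zero voxel count.
#'
#' @param map numeric vector or 3-D array over the full analysis grid.
#' @param atlas a `gm_atlas` on the same grid.
#' @param mask a `brain_mask` on the same grid (optional; default all
#'   voxels).
#' @return data.frame: `label`, `name`, `hemisphere`, `mean_effect`,
#'   `n_voxels`.
#' @export
roi_mean_effect <- function(map, atlas, mask = NULL) {
  stopifnot(inherits(atlas, "gm_atlas"))
  map <- as.numeric(map)
  if (length(map) != prod(atlas$grid_shape))
    stop("map and atlas are on different grids")
  keep <- if (is.null(mask)) rep(TRUE, length(map)) else {
    stopifnot(inherits(mask, "brain_mask"),
              all(mask$grid_shape == atlas$grid_shape))
    mask$mask
  }
  lab <- as.integer(atlas$labels)
  use <- keep & lab > 0 & !is.na(map)
  sums <- tapply(map[use], lab[use], sum)
  cnts <- tapply(map[use], lab[use], length)
  out <- atlas$table
  idx <- match(as.character(out$label), names(sums))
  out$mean_effect <- as.numeric(sums[idx] / cnts[idx])
  out$n_voxels <- ifelse(is.na(idx), 0L, as.integer(cnts[idx]))
  out
}

#' Rank regions by mean linear age effect
#'
#' Sorts ROIs ascending by mean effect, so rank 1 is the most negative
#' (fastest-declining) region. Ties are broken by atlas label order, and
#' the tie rule is recorded.
#'
#' @param roi_effects data.frame from [roi_mean_effect()] (columns `label`,
#'   `mean_effect`, and optionally `hemisphere`, `name`).
#' @param hemisphere optional `"L"` or `"R"` filter.
#' @return data.frame of class `roi_ranking`, sorted, with a `rank` column
#'   (a permutation of `1..n`); the tie rule is in `attr(, "ties")`.
#' @export
rank_rois <- function(roi_effects, hemisphere = NULL) {
  stopifnot(all(c("label", "mean_effect") %in% names(roi_effects)))
  x <- roi_effects
  if (!is.null(hemisphere)) {
    stopifnot(hemisphere %in% c("L", "R"), "hemisphere" %in% names(x))
    x <- x[x$hemisphere == hemisphere, , drop = FALSE]
  }
  if (anyNA(x$mean_effect)) stop("mean effects must be finite for ranking")
  ord <- order(x$mean_effect, x$label)
  x <- x[ord, , drop = FALSE]
  x$rank <- seq_len(nrow(x))
  rownames(x) <- NULL
  attr(x, "ties") <- "ties broken by ascending atlas label"
  class(x) <- c("roi_ranking", "data.frame")
  x
}

#' Kolmogorov-Smirnov normality check per region
#'
#' Lilliefors-corrected one-sample KS test against a normal distribution
#' with estimated mean and SD, applied to each row of a matrix (regions x
#' subjects) of data or model residuals. Constant rows are reported with
#' p = 0 and flagged.
#'
#' @param x numeric matrix (regions x observations) or vector.
#' @return data.frame: `roi`, `statistic`, `p`, `constant` flag.
#' @export
ks_normality <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) < 8) stop("at least 8 observations per region are required")
  res <- apply(x, 1, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, 0, 1))
    kt <- nortest::lillie.test(v)
    c(unname(kt$statistic), kt$p.value, 0)
  })
  data.frame(roi = rownames(x) %||% seq_len(nrow(x)),
             statistic = res[1, ], p = res[2, ],
             constant = res[3, ] == 1, row.names = NULL)
}

#' Kendall rank concordance between mode rankings
#'
#' @param effects_by_mode named list of per-ROI mean-effect vectors (same
#'   ROI order in each).
#' @return matrix of pairwise Kendall's tau between the mode-wise effect
#'   orderings.
#' @export
ranking_concordance <- function(effects_by_mode) {
  stopifnot(is.list(effects_by_mode), length(effects_by_mode) >= 2)
  n <- length(effects_by_mode)
  out <- matrix(1, n, n, dimnames = list(names(effects_by_mode),
                                         names(effects_by_mode)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tau <- stats::cor(effects_by_mode[[i]], effects_by_mode[[j]],
                      method = "kendall")
    out[i, j] <- out[j, i] <- tau
  }
  out
}

#' Average voxel data within regions
#'
#' @param set a `gm_volume_set`.
#' @param atlas a `gm_atlas` on the same grid.
#' @param mask optional `brain_mask`.
#' @return subjects x regions matrix of ROI-mean GM, columns named by label.
#' @export
roi_means <- function(set, atlas, mask = NULL) {
  stopifnot(inherits(set, "gm_volume_set"),
            all(atlas$grid_shape == set$grid_shape))
  keep <- if (is.null(mask)) rep(TRUE, ncol(set$data)) else mask$mask
  lab <- as.integer(atlas$labels)
  out <- sapply(atlas$table$label, function(l) {
    idx <- which(keep & lab == l)
    if (!length(idx)) return(rep(NA_real_, nrow(set$data)))
    rowMeans(set$data[, idx, drop = FALSE])
  })
  colnames(out) <- atlas$table$label
  rownames(out) <- rownames(set$data)
  out
}

#' Per-ROI age-trajectory summaries under each adjustment mode
#'
#' Refits the voxelwise suite's GLMs at ROI level (per-subject ROI-mean GM)
#' for the requested modes, and returns, per region and mode, the
#' sex-averaged linear slope, its one-tailed decline p-value, and the
#' partial R-squared of the linear age terms. TIV-residualized ROI values
#' (residuals after removing the TIV fit, with the region mean added back)
#' are attached for plotting age trajectories.
#'
#' Note the two aggregation routes: [roi_mean_effect()] averages voxelwise
#' *parameter estimates* for ranking, while this function *refits* on
#' ROI-mean data; both are provided and labelled distinctly.
#'
#' @param Y_roi subjects x regions matrix from [roi_means()].
#' @param cohort the matching `gm_cohort`.
#' @param modes adjustment modes to run (default the three model-based
#'   modes; `"local_scaling"` adds a scaled copy of the `"none"` slopes).
#' @return data.frame (long format): `roi`, `mode`, `slope`, `p_one_tailed`,
#'   `partial_r2_linear`; TIV-residualized values in
#'   `attr(, "tiv_residualized")` (subjects x regions, list per mode).
#' @export
roi_age_summary <- function(Y_roi, cohort,
                            modes = c("none", "global_scaling",
                                      "local_covariation")) {
  bad <- setdiff(modes, c("none", "global_scaling", "local_covariation",
                          "local_scaling"))
  if (length(bad)) stop("unknown adjustment mode(s): ", paste(bad, collapse = ", "))
  res <- list(); residualized <- list()
  for (m in modes) {
    fit <- vbm_fit(Y_roi, cohort, adjustment = m)
    # linear-age partial R2: drop the linear columns from the design
    lin <- grep("^age_lin_", fit$design$roles)
    red_design <- fit$design
    red_design$X <- red_design$X[, -lin, drop = FALSE]
    red_design$roles <- red_design$roles[-lin]
    M <- if (m == "global_scaling")
      apply_global_scaling(Y_roi, cohort$tgm) else Y_roi
    red <- fit_ols(t(M), red_design)
    pr2 <- partial_r2(fit, red)
    slope <- if (m == "local_scaling") fit$scaling$scaled_slope
             else fit$contrast$effect
    res[[m]] <- data.frame(roi = colnames(Y_roi) %||% seq_len(ncol(Y_roi)),
                           mode = m, slope = slope,
                           p_one_tailed = fit$contrast$p,
                           partial_r2_linear = pr2,
                           row.names = NULL)
    # residuals after TIV removal, region mean restored, for plotting
    tiv_c <- fit$design$X[, "tiv"]
    beta_tiv <- fit$betas["tiv", ]
    residualized[[m]] <- M - outer(tiv_c, beta_tiv)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "tiv_residualized") <- residualized
  out
}
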