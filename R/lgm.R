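#' Voxelwise coupling between local mean GM and the linear age slope
#'
#' Correlates, across in-mask voxels, the sex-averaged linear age slope with
#' the constant term of the GLM (local mean gray matter, LGM), then repeats
#' the correlation after Local Scaling (slope divided by LGM). A negative
#' raw correlation means voxels with more gray matter show steeper
#' age-related decline — the signature of partial-volume coupling. Local
#' Scaling removes the within-region proportional component of that
#' coupling, so the scaled correlation is expected to shrink in magnitude.
#'
#' The sampling error of the constant-term estimate is ignored when
#' treating LGM as an axis; its average relative standard error across
#' voxels is reported for transparency.
#'
#' @param fit a `vbm_fit` from the unadjusted (`"none"`) model on voxel
#'   data.
#' @param floor Local Scaling exclusion floor on `|LGM|` (as in
#'   [local_scale_slopes()]); exclusions apply identically to both
#'   correlations' scaled arm.
#' @param nbins number of bins per axis of the 2-D density histogram
#'   summarizing the scatter (default 50).
#' @return object of class `slope_lgm`: `r_raw`, `p_raw`, `r_scaled`,
#'   `p_scaled`, `n_voxels`, `n_excluded`, `mean_lgm_rel_error`, and
#'   `hist2d` (list with `x_breaks`, `y_breaks`, `counts`).
#' @export
slope_vs_lgm <- function(fit, floor = 1e-3, nbins = 50) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!is.null(fit$adjustment) &&
      !fit$adjustment %in% c("none", "local_scaling"))
    stop("slope-LGM coupling is defined on the unadjusted ('none') fit")
  ls <- local_scale_slopes(fit, floor = floor)
  keep <- setdiff(seq_along(ls$slope), ls$excluded)
  if (length(keep) < 10) stop("fewer than 10 usable voxels")
  slope <- ls$slope[keep]; lgm <- ls$lgm[keep]
  raw <- stats::cor.test(slope, lgm)
  scaled <- stats::cor.test(ls$scaled_slope[keep], lgm)
  # relative error of the constant-term estimate, averaged across voxels
  cons <- grep("^const_", fit$design$roles, value = TRUE)
  wts <- as.numeric(fit$design$sex_counts[sub("const_", "", cons)])
  wts <- wts / sum(wts)
  w <- stats::setNames(numeric(length(fit$design$roles)), fit$design$roles)
  w[cons] <- wts
  wvw <- drop(t(w) %*% fit$xtx_inv %*% w)
  se_const <- sqrt(fit$sigma2[keep] * wvw)
  rel_err <- mean(se_const / abs(lgm))
  h <- list(
    x_breaks = seq(min(lgm), max(lgm), length.out = nbins + 1),
    y_breaks = seq(min(slope), max(slope), length.out = nbins + 1)
  )
  xi <- pmin(findInterval(lgm, h$x_breaks, rightmost.closed = TRUE), nbins)
  yi <- pmin(findInterval(slope, h$y_breaks, rightmost.closed = TRUE), nbins)
  h$counts <- unclass(table(factor(xi, 1:nbins), factor(yi, 1:nbins)))
  structure(list(r_raw = unname(raw$estimate), p_raw = raw$p.value,
                 r_scaled = unname(scaled$estimate), p_scaled = scaled$p.value,
                 n_voxels = length(keep), n_excluded = length(ls$excluded),
                 mean_lgm_rel_error = rel_err, hist2d = h),
            class = "slope_lgm")
}

#' @export
print.slope_lgm <- function(x, ...) {
  cat(sprintf("Slope-LGM coupling over %d voxels (%d excluded):\n",
              x$n_voxels, x$n_excluded))
  cat(sprintf("  raw: Pearson r = %.3f (p = %.3g)\n", x$r_raw, x$p_raw))
  cat(sprintf("  after Local Scaling: r = %.3f (p = %.3g)\n",
              x$r_scaled, x$p_scaled))
  cat(sprintf("  mean relative error of the LGM estimate: %.2f%%\n",
              100 * x$mean_lgm_rel_error))
  invisible(x)
}

#' Plot the slope-vs-LGM density scatter
#'
#' @param x a `slope_lgm` result.
#' @param ... passed to [graphics::image()].
#' @export
plot.slope_lgm <- function(x, ...) {
  graphics::image(x$hist2d$x_breaks, x$hist2d$y_breaks,
                  log1p(x$hist2d$counts),
                  xlab = "local mean GM (constant term)",
                  ylab = "linear age slope", ...)
  graphics::title(sprintf("r = %.2f (raw), %.2f (scaled)",
                          x$r_raw, x$r_scaled))
  invisible(x)
}
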