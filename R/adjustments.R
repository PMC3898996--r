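#' Global Scaling: divide each subject's image by their TGM
#'
#' Proportional adjustment for total gray matter: every voxel of subject `i`
#' is divided by that subject's TGM. By default the scaled values are then
#' multiplied by the cohort-mean TGM so they stay in interpretable GM
#' density units (this grand-mean scaling changes parameter magnitudes but
#' not t- or p-statistics).
#'
#' @param Y a `gm_volume_set`, or a subjects x units matrix.
#' @param tgm per-subject total gray matter (mL); must be positive.
#' @param grand_mean_scale multiply back by `mean(tgm)` (default `TRUE`).
#' @return object of the same type as `Y`, scaled; subject order preserved.
#' @export
apply_global_scaling <- function(Y, tgm, grand_mean_scale = TRUE) {
  is_set <- inherits(Y, "gm_volume_set")
  M <- if (is_set) Y$data else Y
  stopifnot(is.matrix(M), length(tgm) == nrow(M))
  bad <- which(tgm <= 0)
  if (length(bad))
    stop("nonpositive TGM for subject(s): ",
         paste(rownames(M)[bad] %||% bad, collapse = ", "))
  scl <- if (grand_mean_scale) mean(tgm) / tgm else 1 / tgm
  M <- M * scl
  if (is_set) gm_volume_set(M, Y$grid_shape, Y$voxel_size, rownames(M)) else M
}

#' Fit the VBM model under a global-adjustment mode
#'
#' The central fitting function of the package. Fits the mass-univariate
#' OLS model (per-sex second-degree age polynomial, per-sex constants, TIV)
#' to every in-mask voxel (or every column of a subjects x units matrix),
#' under one of four treatments of total gray matter:
#'
#' * `"none"` — raw data, no TGM term;
#' * `"global_scaling"` — data divided by each subject's TGM
#'   ([apply_global_scaling()]) before fitting, no TGM term;
#' * `"local_covariation"` — raw data with mean-centered TGM as an
#'   additional per-voxel covariate;
#' * `"local_scaling"` — fitted exactly as `"none"`, then the sex-averaged
#'   linear slope map is divided by the constant-term (local mean GM) map
#'   ([local_scale_slopes()]). Statistics are untouched: Local Scaling is a
#'   descriptive rescaling of effect sizes.
#'
#' TIV is always included as a covariate of no interest. The canonical
#' decline contrast (sex-averaged linear age slope, lower tail) is computed
#' on every fit.
#'
#' @param Y a `gm_volume_set` (smoothed analysis images) or a subjects x
#'   units numeric matrix (e.g. ROI means).
#' @param cohort the matching `gm_cohort` (same subject order).
#' @param adjustment one of `"none"`, `"global_scaling"`,
#'   `"local_covariation"`, `"local_scaling"`.
#' @param mask optional `brain_mask` restricting voxels (required to compare
#'   modes on identical units); ignored for matrix input.
#' @param grand_mean_scale see [apply_global_scaling()].
#' @param keep_data keep the (possibly scaled) response matrix in the fit.
#' @return object of class `vbm_fit` (inherits `glm_fit`), with elements
#'   `adjustment`, `contrast` (the decline contrast), `lgm` (sex-weighted
#'   constants), `scaling` (a `local_scaling` object when
#'   `adjustment = "local_scaling"`), `mask`, plus all `glm_fit` fields.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_decade = 10, seed = 3))
#' atl <- synthetic_atlas(c(12, 12, 12), block = 4, n_per_hemisphere = 6)
#' regs <- region_specs_default(atl, seed = 3)
#' sim <- generate_gm_images(coh, regs, atl,
#'                           image_gen_spec(grid_shape = c(12, 12, 12),
#'                                          smoothing_fwhm = 0, seed = 3))
#' fit <- vbm_fit(sim$unsmoothed, sim$cohort, adjustment = "none")
#' fit
vbm_fit <- function(Y, cohort,
                    adjustment = c("none", "global_scaling",
                                   "local_covariation", "local_scaling"),
                    mask = NULL, grand_mean_scale = TRUE, keep_data = TRUE) {
  adjustment <- match.arg(adjustment)
  is_set <- inherits(Y, "gm_volume_set")
  M <- if (is_set) Y$data else as.matrix(Y)
  if (nrow(M) != nrow(cohort))
    stop("subject count mismatch between data and cohort")
  unit_ids <- NULL
  if (is_set && !is.null(mask)) {
    stopifnot(inherits(mask, "brain_mask"),
              all(mask$grid_shape == Y$grid_shape))
    unit_ids <- which(mask$mask)
    M <- M[, unit_ids, drop = FALSE]
  } else if (!is_set) {
    unit_ids <- colnames(M) %||% seq_len(ncol(M))
  }

  if (adjustment == "global_scaling") {
    if (anyNA(cohort$tgm)) stop("global_scaling requires cohort$tgm")
    M <- apply_global_scaling(M, cohort$tgm, grand_mean_scale)
  }
  design <- build_design(cohort,
                         include_tgm = (adjustment == "local_covariation"))
  fit <- fit_ols(t(M), design, unit_ids = unit_ids, keep_data = keep_data)
  fit$adjustment <- adjustment
  fit$mask <- mask
  fit$lgm <- lgm_constant(fit)
  fit$contrast <- contrast_t(fit, age_linear_weights(design), tail = "lower")
  class(fit) <- c("vbm_fit", class(fit))
  if (adjustment == "local_scaling") fit$scaling <- local_scale_slopes(fit)
  fit
}

#' Divide the linear age-slope map by the local-mean-GM map
#'
#' Local Scaling re-expresses each unit's sex-averaged linear age slope as a
#' fraction of that unit's mean gray matter (the sex-weighted constant
#' term), giving units of "fraction of local mean GM per year". Test
#' statistics are carried over unchanged from the unadjusted fit. Units
#' whose constant falls below `floor` in absolute value are excluded
#' (`NA` in the scaled map) to avoid division blow-up in low-GM voxels, and
#' reported.
#'
#' @param fit a `vbm_fit` (or `glm_fit`) from the unadjusted (`"none"`)
#'   model.
#' @param floor minimum `|constant|` (GM density units) for inclusion.
#' @return object of class `local_scaling`: `scaled_slope` (per unit, `NA`
#'   where excluded), `slope`, `lgm`, `excluded` (indices), and the
#'   unadjusted fit's `t` and `p` carried over verbatim.
#' @export
local_scale_slopes <- function(fit, floor = 1e-3) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!is.null(fit$adjustment) &&
      !fit$adjustment %in% c("none", "local_scaling"))
    stop("local scaling must start from the unadjusted ('none') fit")
  ctr <- fit$contrast %||% contrast_t(fit, age_linear_weights(fit$design),
                                      tail = "lower")
  slope <- ctr$effect
  lgm <- lgm_constant(fit)
  excluded <- which(abs(lgm) < floor)
  scaled <- slope / lgm
  scaled[excluded] <- NA_real_
  structure(list(scaled_slope = scaled, slope = slope, lgm = lgm,
                 excluded = excluded, floor = floor,
                 t = ctr$t, p = ctr$p, unit_ids = fit$unit_ids),
            class = "local_scaling")
}

#' @export
print.local_scaling <- function(x, ...) {
  cat(sprintf("Local Scaling: %d units (%d excluded below |LGM| = %g)\n",
              length(x$scaled_slope), length(x$excluded), x$floor))
  cat(sprintf("  scaled slope range [%.4g, %.4g] per year (fraction of LGM)\n",
              min(x$scaled_slope, na.rm = TRUE),
              max(x$scaled_slope, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.vbm_fit <- function(x, ...) {
  cat(sprintf("VBM fit (%s): %d units, %d subjects, df = %d\n",
              x$adjustment, ncol(x$betas), nrow(x$design$X), x$df))
  cat(sprintf("  decline contrast: %d units with p < .05 uncorrected\n",
              sum(x$contrast$p < 0.05)))
  invisible(x)
}

#' @export
summary.vbm_fit <- function(object, fwe_alpha = 0.05, ...) {
  bonf <- pmin(1, length(object$contrast$p) * object$contrast$p)
  out <- list(adjustment = object$adjustment,
              n_subjects = nrow(object$design$X),
              n_units = ncol(object$betas),
              df = object$df,
              slope_range = range(object$contrast$effect),
              n_sig_uncorrected = sum(object$contrast$p < 0.05),
              n_sig_fwe = sum(bonf < fwe_alpha),
              fwe_alpha = fwe_alpha,
              lgm_range = range(object$lgm))
  class(out) <- "summary.vbm_fit"
  out
}

#' @export
print.summary.vbm_fit <- function(x, ...) {
  cat(sprintf("VBM analysis, adjustment = %s\n", x$adjustment))
  cat(sprintf("  %d subjects, %d units, df = %d\n", x$n_subjects, x$n_units, x$df))
  cat(sprintf("  sex-averaged linear slope range: [%.4g, %.4g] per year\n",
              x$slope_range[1], x$slope_range[2]))
  cat(sprintf("  decline: %d units p < .05 uncorrected; %d at Bonferroni FWE %.2f\n",
              x$n_sig_uncorrected, x$n_sig_fwe, x$fwe_alpha))
  invisible(x)
}

#' Run the four adjustment modes as a comparable suite
#'
#' Fits `"none"`, `"global_scaling"`, `"local_covariation"` and
#' `"local_scaling"` on identical data, mask and subject order, so outputs
#' are directly comparable unit by unit. A failure in one mode (caught and
#' stored) does not abort the others.
#'
#' @inheritParams vbm_fit
#' @return named list of `vbm_fit`s (or `try-error`s), class
#'   `vbm_fit_suite`.
#' @export
fit_adjustment_suite <- function(Y, cohort, mask = NULL,
                                 grand_mean_scale = TRUE, keep_data = TRUE) {
  modes <- c("none", "global_scaling", "local_covariation", "local_scaling")
  fits <- lapply(modes, function(m) {
    tryCatch(vbm_fit(Y, cohort, adjustment = m, mask = mask,
                     grand_mean_scale = grand_mean_scale,
                     keep_data = keep_data),
             error = function(e) structure(conditionMessage(e),
                                           class = "vbm_fit_error"))
  })
  names(fits) <- modes
  class(fits) <- "vbm_fit_suite"
  fits
}

#' @export
print.vbm_fit_suite <- function(x, ...) {
  for (m in names(x)) {
    if (inherits(x[[m]], "vbm_fit_error"))
      cat(sprintf("%-18s FAILED: %s\n", m, unclass(x[[m]])))
    else
      cat(sprintf("%-18s %d units, %d sig. at p < .05\n", m,
                  ncol(x[[m]]$betas), sum(x[[m]]$contrast$p < 0.05)))
  }
  invisible(x)
}
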