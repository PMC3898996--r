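# Lean OLS core shared by the public fitter and the permutation loop.
# X: n x p (assumed full rank, pre-checked); Yt: n x units.
# Returns betas (p x units), rss (units), df.
ols_core <- function(X, Yt, xtx_inv = NULL) {
  if (is.null(xtx_inv)) xtx_inv <- chol2inv(chol(crossprod(X)))
  betas <- xtx_inv %*% crossprod(X, Yt)
  resid <- Yt - X %*% betas
  list(betas = betas, rss = colSums(resid^2), df = nrow(X) - ncol(X),
       xtx_inv = xtx_inv)
}

#' Fit mass-univariate ordinary least squares
#'
#' Fits the same linear model independently to every unit (voxel or ROI):
#' one pass of normal equations shared across units.
#'
#' @param Y numeric matrix, units x subjects.
#' @param design a `vbm_design`.
#' @param unit_ids optional unit identifiers (voxel indices or ROI labels).
#' @param keep_data keep `Y` inside the fit (needed by [residuals.glm_fit()]
#'   and permutation-based FWE correction). Default `TRUE`.
#' @return object of class `glm_fit`: `betas` (p x units), `sigma2`
#'   (residual variance per unit, RSS/df), `rss`, `df`, `design`,
#'   `unit_ids`, and `Y` when kept.
#' @export
fit_ols <- function(Y, design, unit_ids = NULL, keep_data = TRUE) {
  stopifnot(inherits(design, "vbm_design"))
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  if (ncol(Y) != nrow(design$X))
    stop("Y must be units x subjects, matching the design's subject count")
  bad <- which(rowSums(!is.finite(Y)) > 0)
  if (length(bad))
    stop("non-finite values in Y for units: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  core <- ols_core(design$X, t(Y))
  if (core$df <= 0) stop("no residual degrees of freedom")
  rownames(core$betas) <- design$roles
  structure(list(betas = core$betas, rss = core$rss,
                 sigma2 = core$rss / core$df, df = core$df,
                 xtx_inv = core$xtx_inv, design = design,
                 unit_ids = unit_ids %||% seq_len(nrow(Y)),
                 Y = if (keep_data) Y else NULL),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Mass-univariate OLS fit: %d units, %d subjects, %d regressors, df = %d\n",
              ncol(x$betas), nrow(x$design$X), nrow(x$betas), x$df))
  invisible(x)
}

#' @export
coef.glm_fit <- function(object, ...) object$betas

#' Residuals of a mass-univariate fit
#' @param object a `glm_fit` fitted with `keep_data = TRUE`.
#' @param ... unused.
#' @return units x subjects residual matrix.
#' @export
residuals.glm_fit <- function(object, ...) {
  if (is.null(object$Y)) stop("fit was created with keep_data = FALSE")
  object$Y - t(object$design$X %*% object$betas)
}

#' Contrast t-statistics and one-tailed p-values
#'
#' Computes `effect = w' beta` per unit, its t-statistic, and the p-value on
#' the requested tail. Decline in the canonical aging contrast is assessed
#' with `tail = "lower"` on the sex-averaged linear age slope (see
#' [age_linear_weights()]).
#'
#' @param fit a `glm_fit`.
#' @param weights numeric contrast weights, length p (may be named by role).
#' @param tail `"lower"`, `"upper"` or `"two"`.
#' @return object of class `vbm_contrast`: `weights`, `effect`, `se`, `t`,
#'   `p`, `tail`, `df`, `unit_ids`.
#' @export
contrast_t <- function(fit, weights, tail = c("lower", "upper", "two")) {
  tail <- match.arg(tail)
  stopifnot(inherits(fit, "glm_fit"))
  if (!is.null(names(weights))) {
    w <- stats::setNames(numeric(length(fit$design$roles)), fit$design$roles)
    w[names(weights)] <- weights
    weights <- w
  }
  if (length(weights) != nrow(fit$betas))
    stop("contrast weights must have one entry per design column")
  effect <- drop(weights %*% fit$betas)
  wvw <- drop(t(weights) %*% fit$xtx_inv %*% weights)
  se <- sqrt(fit$sigma2 * wvw)
  tstat <- effect / se
  p <- switch(tail,
              lower = stats::pt(tstat, fit$df),
              upper = stats::pt(tstat, fit$df, lower.tail = FALSE),
              two = 2 * stats::pt(-abs(tstat), fit$df))
  structure(list(weights = weights, effect = effect, se = se, t = tstat,
                 p = p, tail = tail, df = fit$df, unit_ids = fit$unit_ids),
            class = "vbm_contrast")
}

#' @export
print.vbm_contrast <- function(x, ...) {
  cat(sprintf("Contrast over %d units (%s tail): t range [%.2f, %.2f], %d with p < .05\n",
              length(x$t), x$tail, min(x$t), max(x$t), sum(x$p < 0.05)))
  invisible(x)
}

#' Partial R-squared of nested models
#'
#' Fraction of the reduced model's residual variance explained by the extra
#' terms of the full model: `(RSS_reduced - RSS_full) / RSS_reduced`.
#'
#' @param fit_full,fit_reduced `glm_fit`s on the same units and subjects;
#'   the reduced design's columns must be a subset of the full design's.
#' @return numeric vector in `[0, 1]`, one value per unit.
#' @export
partial_r2 <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "glm_fit"), inherits(fit_reduced, "glm_fit"))
  if (!all(fit_reduced$design$roles %in% fit_full$design$roles))
    stop("models are not nested: reduced design has columns absent from the full design")
  if (nrow(fit_reduced$design$X) != nrow(fit_full$design$X) ||
      length(fit_reduced$rss) != length(fit_full$rss))
    stop("models are not comparable: different subjects or units")
  out <- (fit_reduced$rss - fit_full$rss) / fit_reduced$rss
  out[fit_reduced$rss == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Familywise-error correction across units
#'
#' Corrects a contrast's per-unit p-values for the multiplicity of the voxel
#' (or ROI) family, by Bonferroni or by max-statistic permutation with
#' Freedman-Lane residual permutation: the nuisance model (all columns with
#' zero contrast weight) is fitted, its residuals are permuted over
#' subjects, the full model is refitted, and the most extreme contrast
#' statistic across units forms the null distribution.
#'
#' @param contrast a `vbm_contrast`.
#' @param fit the `glm_fit` the contrast came from (required for
#'   permutation; must have been fitted with `keep_data = TRUE`).
#' @param method `"bonferroni"` or `"permutation_maxT"`.
#' @param n_perm number of permutations (permutation p-values live on the
#'   grid `1/(n_perm+1), ..., 1`).
#' @param seed integer seed (required for permutation).
#' @return the contrast with an added `p_fwe` element (and `n_perm`,
#'   `method`). Corrected p-values never fall below the uncorrected ones.
#' @export
fwe_correct <- function(contrast, fit = NULL,
                        method = c("bonferroni", "permutation_maxT"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(contrast, "vbm_contrast"))
  m <- length(contrast$p)
  if (method == "bonferroni") {
    p_fwe <- pmin(1, m * contrast$p)
  } else {
    if (is.null(fit) || is.null(fit$Y))
      stop("permutation correction needs the fit with its data (keep_data = TRUE)")
    if (is.null(seed)) stop("permutation correction requires a seed")
    if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
    set.seed(seed)
    X <- fit$design$X
    w <- contrast$weights
    nuis <- which(w == 0)
    Z <- X[, nuis, drop = FALSE]
    Yt <- t(fit$Y)
    red <- ols_core(Z, Yt)
    fitted_z <- Z %*% red$betas
    R <- Yt - fitted_z
    xtx_inv <- fit$xtx_inv
    wvw <- drop(t(w) %*% xtx_inv %*% w)
    n <- nrow(X); df <- fit$df
    stat <- function(Ystar) {
      core <- ols_core(X, Ystar, xtx_inv = xtx_inv)
      eff <- drop(w %*% core$betas)
      eff / sqrt(core$rss / df * wvw)
    }
    extreme <- switch(contrast$tail,
                      lower = function(t) min(t),
                      upper = function(t) max(t),
                      two = function(t) max(abs(t)))
    null_max <- vapply(seq_len(n_perm), function(b) {
      extreme(stat(fitted_z + R[sample.int(n), , drop = FALSE]))
    }, 0)
    obs <- contrast$t
    p_fwe <- switch(contrast$tail,
                    lower = vapply(obs, function(t0)
                      (1 + sum(null_max <= t0)) / (n_perm + 1), 0),
                    upper = vapply(obs, function(t0)
                      (1 + sum(null_max >= t0)) / (n_perm + 1), 0),
                    two = vapply(abs(obs), function(t0)
                      (1 + sum(null_max >= t0)) / (n_perm + 1), 0))
  }
  contrast$p_fwe <- pmax(pmin(p_fwe, 1), contrast$p)
  contrast$fwe_method <- method
  if (method == "permutation_maxT") contrast$n_perm <- n_perm
  contrast
}

#' Fit a second-order age trend to a global tissue volume
#'
#' Models one per-subject global measure (TIV, TGM, TWM or TCSF) as a
#' centered second-degree polynomial of age, pooled across sexes, optionally
#' after covarying out TIV. Returns, for the linear and quadratic terms, the
#' parameter estimate, a one-tailed p-value (taken on the tail of the
#' observed sign), and the partial R-squared relative to dropping that term;
#' also the combined age partial R-squared and the percent change of the
#' fitted curve over the cohort's age range.
#'
#' @param values numeric vector, one global volume per subject (mL).
#' @param cohort a `gm_cohort`.
#' @param covary_tiv covary out TIV before assessing the age trend. Must be
#'   `FALSE` when `values` *is* the TIV.
#' @return object of class `global_trend`.
#' @export
fit_global_trend <- function(values, cohort, covary_tiv = TRUE) {
  stopifnot(length(values) == nrow(cohort))
  if (covary_tiv && isTRUE(all.equal(as.numeric(values), as.numeric(cohort$tiv))))
    stop("cannot covary TIV out of TIV itself; use covary_tiv = FALSE")
  a <- cohort$age - mean(cohort$age)
  q <- a^2 - mean(a^2)
  X <- cbind(const = 1, age_lin = a, age_quad = q)
  if (covary_tiv) X <- cbind(X, tiv = cohort$tiv - mean(cohort$tiv))
  n <- nrow(X)
  fit <- stats::lm.fit(X, values)
  rss <- sum(fit$residuals^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  terms <- c("age_lin", "age_quad")
  per_term <- lapply(terms, function(tm) {
    j <- match(tm, colnames(X))
    beta <- fit$coefficients[j]
    se <- sqrt(sigma2 * xtx_inv[j, j])
    tstat <- beta / se
    p1 <- if (tstat < 0) stats::pt(tstat, df) else stats::pt(tstat, df, lower.tail = FALSE)
    red <- stats::lm.fit(X[, -j, drop = FALSE], values)
    rss_red <- sum(red$residuals^2)
    list(beta = unname(beta), t = unname(tstat), p_one_tailed = unname(p1),
         partial_r2 = (rss_red - rss) / rss_red)
  })
  names(per_term) <- terms
  red_age <- stats::lm.fit(X[, setdiff(colnames(X), terms), drop = FALSE], values)
  rss_red <- sum(red_age$residuals^2)
  age_r2 <- (rss_red - rss) / rss_red
  # percent change of the fitted age curve over the observed range
  rng <- range(cohort$age)
  curve_at <- function(age) {
    ac <- age - mean(cohort$age)
    fit$coefficients["const"] + fit$coefficients["age_lin"] * ac +
      fit$coefficients["age_quad"] * (ac^2 - mean(a^2))
  }
  pct_change <- 100 * (curve_at(rng[2]) - curve_at(rng[1])) / curve_at(rng[1])
  structure(list(linear = per_term$age_lin, quadratic = per_term$age_quad,
                 age_partial_r2 = age_r2, percent_change = unname(pct_change),
                 covary_tiv = covary_tiv, n = n, df = df,
                 coefficients = fit$coefficients),
            class = "global_trend")
}

#' @export
print.global_trend <- function(x, ...) {
  cat(sprintf("Global age trend (%s): L beta = %.4g (p = %.3g, pR2 = %.3f); Q beta = %.4g (p = %.3g, pR2 = %.3f)\n",
              if (x$covary_tiv) "TIV covaried" else "raw",
              x$linear$beta, x$linear$p_one_tailed, x$linear$partial_r2,
              x$quadratic$beta, x$quadratic$p_one_tailed, x$quadratic$partial_r2))
  cat(sprintf("  combined age partial R2 = %.3f; fitted change over age range = %.2f%%\n",
              x$age_partial_r2, x$percent_change))
  invisible(x)
}
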