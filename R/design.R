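#' Build the VBM design matrix
#'
#' Constructs the subjects x regressors design used by every model in the
#' suite: a second-degree polynomial expansion of age *separately for each
#' sex* (sex-partitioned linear and quadratic age columns), per-sex
#' constants, mean-centered TIV, and optionally mean-centered TGM (the Local
#' Covariation covariate).
#'
#' Age columns are centered within the sex they belong to, and quadratic
#' columns are additionally centered so they sum to zero within sex. With
#' this centering every non-constant column is orthogonal to the
#' sex-weighted constant direction, so the sex-weighted average of the two
#' constants equals the per-unit mean of the response (the "LGM identity":
#' the constant-term image is the mean GM image). The centering means are
#' recorded so a test half can be projected through a training half's
#' centering (needed by the cross-validation module).
#'
#' @param cohort a `gm_cohort` (needs `age`, `sex`, `tiv`, and `tgm` when
#'   `include_tgm`).
#' @param include_tgm include the mean-centered TGM covariate.
#' @param centering optional centering record from a previous design (as
#'   stored in `$centering`), used to centre this cohort's columns with
#'   *those* means instead of its own.
#' @return object of class `vbm_design`: list with `X` (matrix), `roles`
#'   (column roles), `centering`, `sex_counts`.
#' @export
build_design <- function(cohort, include_tgm = FALSE, centering = NULL) {
  stopifnot(all(c("age", "sex", "tiv") %in% names(cohort)))
  if (include_tgm && (is.null(cohort$tgm) || anyNA(cohort$tgm)))
    stop("'tgm' is required (and must be complete) when include_tgm = TRUE")
  if (include_tgm && stats::sd(cohort$tgm) == 0) {
    warning("TGM is constant across subjects; dropping the degenerate covariate")
    include_tgm <- FALSE
  }
  sexes <- c("M", "F")
  present <- sexes[sexes %in% cohort$sex]
  if (length(present) < 2L)
    warning("single-sex cohort: columns for the absent sex are dropped")

  n <- nrow(cohort)
  if (is.null(centering)) {
    age_mean <- vapply(present, function(s) mean(cohort$age[cohort$sex == s]), 0)
    age_sq_mean <- vapply(present, function(s) {
      a <- cohort$age[cohort$sex == s] - age_mean[s]
      mean(a^2)
    }, 0)
    centering <- list(age_mean = age_mean, age_sq_mean = age_sq_mean,
                      tiv_mean = mean(cohort$tiv),
                      tgm_mean = if (include_tgm) mean(cohort$tgm) else NA_real_)
  }

  cols <- list(); roles <- character()
  for (s in present) {
    is_s <- cohort$sex == s
    a <- ifelse(is_s, cohort$age - centering$age_mean[s], 0)
    q <- ifelse(is_s, a^2 - centering$age_sq_mean[s], 0)
    cols[[paste0("age_lin_", s)]] <- a
    cols[[paste0("age_quad_", s)]] <- q
    roles <- c(roles, paste0("age_lin_", s), paste0("age_quad_", s))
  }
  for (s in present) {
    cols[[paste0("const_", s)]] <- as.numeric(cohort$sex == s)
    roles <- c(roles, paste0("const_", s))
  }
  cols[["tiv"]] <- cohort$tiv - centering$tiv_mean
  roles <- c(roles, "tiv")
  if (include_tgm) {
    cols[["tgm"]] <- cohort$tgm - centering$tgm_mean
    roles <- c(roles, "tgm")
  }

  X <- do.call(cbind, cols)
  colnames(X) <- roles
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, roles = roles, centering = centering,
                 sex_counts = table(factor(cohort$sex, levels = present))),
            class = "vbm_design")
}

#' @export
print.vbm_design <- function(x, ...) {
  cat(sprintf("VBM design: %d subjects x %d regressors [%s]\n",
              nrow(x$X), ncol(x$X), paste(x$roles, collapse = ", ")))
  invisible(x)
}

#' Contrast weights for the sex-averaged linear age effect
#'
#' The canonical aging contrast: the mean of the per-sex linear age slopes,
#' weights 1/2 and 1/2 (or 1 for a single-sex design). Decline is assessed
#' by testing this contrast on the lower tail.
#'
#' @param design a `vbm_design` (or a fit carrying one).
#' @return named numeric weight vector over the design columns.
#' @export
age_linear_weights <- function(design) {
  if (inherits(design, "vbm_fit")) design <- design$design
  w <- stats::setNames(numeric(length(design$roles)), design$roles)
  lin <- grep("^age_lin_", design$roles, value = TRUE)
  w[lin] <- 1 / length(lin)
  w
}

#' Sex-weighted constant term (the LGM image)
#'
#' With the package's within-sex centering, the weighted average of the
#' per-sex constants (weights = sex proportions) equals the per-unit mean of
#' the response across all subjects, i.e. the local mean gray matter.
#'
#' @param fit a `vbm_fit` or `glm_fit`.
#' @return numeric vector, one value per unit.
#' @export
lgm_constant <- function(fit) {
  design <- fit$design
  cons <- grep("^const_", design$roles, value = TRUE)
  wts <- as.numeric(design$sex_counts[sub("const_", "", cons)])
  wts <- wts / sum(wts)
  drop(wts %*% fit$betas[cons, , drop = FALSE])
}
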