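#' Configure split-half cross-validation
#'
#' @param n_iterations number of random split-half iterations (default 1000;
#'   summaries are medians and are stable well below 10,000 — stability is
#'   itself tested).
#' @param stratify `"none"` (default) or `"by_sex_and_decade"`: split each
#'   sex-by-decade cell as evenly as possible.
#' @param seed master seed; each iteration's split derives its own child
#'   seed from `(seed, iteration)`.
#' @param test_centering `"train"` (default) or `"test"`: which half's
#'   centering means are used to build the test design.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 1000,
                      stratify = c("none", "by_sex_and_decade"),
                      seed = 1L, test_centering = c("train", "test")) {
  stratify <- match.arg(stratify)
  test_centering <- match.arg(test_centering)
  if (n_iterations < 1) stop_config("n_iterations", "must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations), stratify = stratify,
                 seed = as.integer(seed), test_centering = test_centering),
            class = "cv_config")
}

#' Full-data age variance explained under both adjustments
#'
#' For each ROI, fits the Global Scaling model (age polynomial + TIV on
#' TGM-scaled data) and the Local Covariation model (age polynomial + TIV +
#' TGM on raw data) to all subjects, and returns the partial R-squared of
#' the combined linear and quadratic age terms for each.
#'
#' @param Y_roi subjects x regions matrix of ROI-mean GM.
#' @param cohort the matching `gm_cohort`.
#' @return data.frame: `roi`, `r2_global_scaling`, `r2_local_covariation`.
#' @export
full_data_r2 <- function(Y_roi, cohort) {
  age_pr2 <- function(M, include_tgm) {
    design <- build_design(cohort, include_tgm = include_tgm)
    fit <- fit_ols(t(M), design, keep_data = FALSE)
    agecols <- grep("^age_", design$roles)
    red <- design
    red$X <- red$X[, -agecols, drop = FALSE]
    red$roles <- red$roles[-agecols]
    partial_r2(fit, fit_ols(t(M), red, keep_data = FALSE))
  }
  data.frame(
    roi = colnames(Y_roi) %||% seq_len(ncol(Y_roi)),
    r2_global_scaling = age_pr2(apply_global_scaling(Y_roi, cohort$tgm), FALSE),
    r2_local_covariation = age_pr2(Y_roi, TRUE),
    row.names = NULL)
}

#' Draw one split-half partition
#'
#' Deterministic given `(cfg$seed, iteration)`. Unstratified splits permute
#' all subjects and cut in half; stratified splits divide each sex-by-decade
#' cell as evenly as possible, with the odd subject of odd-sized cells
#' assigned to train and test alternately across cells (recorded).
#'
#' @param cohort a `gm_cohort`.
#' @param cfg a [cv_config()].
#' @param iteration iteration number (>= 1).
#' @return list with integer vectors `train` and `test` (disjoint, covering
#'   all subjects) and `odd_rule`.
#' @export
split_half <- function(cohort, cfg, iteration) {
  n <- nrow(cohort)
  if (n < 4) stop("need at least 4 subjects to split")
  set.seed(child_seed(cfg$seed, paste0("split-", iteration)))
  if (cfg$stratify == "none") {
    perm <- sample.int(n)
    train <- perm[seq_len(n %/% 2)]
  } else {
    cell <- interaction(cohort$sex, cohort$decade, drop = TRUE)
    train <- integer(0)
    odd_to_train <- TRUE
    for (cl in levels(cell)) {
      idx <- sample(which(cell == cl))
      k <- length(idx) %/% 2
      if (length(idx) %% 2 == 1 && odd_to_train) k <- k + 1
      if (length(idx) %% 2 == 1) odd_to_train <- !odd_to_train
      train <- c(train, idx[seq_len(k)])
    }
  }
  list(train = sort(train), test = sort(setdiff(seq_len(n), train)),
       odd_rule = "odd cells alternate the extra subject between halves")
}

# Residualize columns of M against design Z (n x q); returns residual matrix.
residualize <- function(M, Z) {
  M - Z %*% (chol2inv(chol(crossprod(Z))) %*% crossprod(Z, M))
}

#' One cross-validation iteration for one adjustment method
#'
#' TRAIN: the method's model is fitted to the training half and the linear
#' and quadratic age-term estimates `beta_train` are kept (train R-squared
#' is the partial R-squared of the age terms in that fit). TEST: the test
#' half is adjusted by its *own* TGM — divided by it (Global Scaling), or
#' with the fit of the test TGM (re-estimated on the test half jointly with
#' the test nuisance) subtracted (Local Covariation) — then the test
#' nuisance (per-sex constants, TIV) is removed, and the adjusted data are
#' predicted by `X_test %*% beta_train` (projected into the same
#' nuisance-orthogonal subspace), where the test age columns are
#' centred with the training half's means by default. Test R-squared is
#' `1 - RSS/TSS` on the adjusted, nuisance-residualized test data; it may
#' be negative (a failure to generalize) and is retained unclipped.
#'
#' @param Y_roi subjects x regions matrix.
#' @param cohort the matching `gm_cohort`.
#' @param split a [split_half()] partition.
#' @param method `"global_scaling"` or `"local_covariation"`.
#' @param test_centering `"train"` or `"test"`.
#' @return list with per-ROI `train_r2`, `test_r2`, `test_r2_cor`
#'   (squared correlation variant).
#' @export
cv_iteration <- function(Y_roi, cohort, split,
                         method = c("global_scaling", "local_covariation"),
                         test_centering = "train") {
  method <- match.arg(method)
  tr <- split$train; te <- split$test
  coh_tr <- cohort[tr, , drop = FALSE]
  coh_te <- cohort[te, , drop = FALSE]

  # ---- train
  M_tr <- Y_roi[tr, , drop = FALSE]
  if (method == "global_scaling")
    M_tr <- apply_global_scaling(M_tr, coh_tr$tgm, grand_mean_scale = FALSE)
  design_tr <- build_design(coh_tr, include_tgm = (method == "local_covariation"))
  fit_tr <- fit_ols(t(M_tr), design_tr, keep_data = FALSE)
  agecols <- grep("^age_", design_tr$roles)
  red <- design_tr
  red$X <- red$X[, -agecols, drop = FALSE]
  red$roles <- red$roles[-agecols]
  train_r2 <- partial_r2(fit_tr, fit_ols(t(M_tr), red, keep_data = FALSE))
  beta_age <- fit_tr$betas[agecols, , drop = FALSE]

  # ---- test
  centering <- if (test_centering == "train") design_tr$centering else NULL
  design_te <- build_design(coh_te, include_tgm = (method == "local_covariation"),
                            centering = centering)
  agecols_te <- grep("^age_", design_te$roles)
  X_age <- design_te$X[, agecols_te, drop = FALSE]
  nuis_cols <- grep("^(const_|tiv$)", design_te$roles)
  Z <- design_te$X[, nuis_cols, drop = FALSE]

  M_te <- Y_roi[te, , drop = FALSE]
  if (method == "global_scaling") {
    M_adj <- apply_global_scaling(M_te, coh_te$tgm, grand_mean_scale = FALSE)
    Y_res <- residualize(M_adj, Z)
  } else {
    tgm_col <- design_te$X[, "tgm", drop = FALSE]
    joint <- cbind(Z, tgm_col)
    beta_joint <- chol2inv(chol(crossprod(joint))) %*% crossprod(joint, M_te)
    M_adj <- M_te - tgm_col %*% beta_joint[ncol(joint), , drop = FALSE]
    Y_res <- residualize(M_adj, Z)
  }
  # map training age columns onto the test design's (roles may differ if a
  # sex is absent from one half; missing roles contribute nothing)
  role_match <- match(design_te$roles[agecols_te], design_tr$roles[agecols])
  if (anyNA(role_match)) stop("age terms missing from the training design")
  pred <- X_age %*% beta_age[role_match, , drop = FALSE]
  # compare data and prediction in the subspace orthogonal to the test
  # nuisance, so nuisance handling cancels from the score; with noiseless
  # data and exactly-recovered age effects this gives test R^2 = 1
  pred <- residualize(pred, Z)
  rss <- colSums((Y_res - pred)^2)
  tss <- colSums(Y_res^2)
  test_r2 <- 1 - rss / tss
  test_r2_cor <- vapply(seq_len(ncol(pred)), function(j) {
    if (stats::sd(pred[, j]) == 0 || stats::sd(Y_res[, j]) == 0) return(NA_real_)
    stats::cor(pred[, j], Y_res[, j])^2
  }, 0)
  list(train_r2 = unname(train_r2), test_r2 = unname(test_r2),
       test_r2_cor = unname(test_r2_cor))
}

#' Run the full split-half cross-validation
#'
#' @param Y_roi subjects x regions matrix of ROI-mean GM.
#' @param cohort the matching `gm_cohort`.
#' @param cfg a [cv_config()].
#' @param methods adjustment methods to compare.
#' @return object of class `vbm_cv`: arrays `train` and `test` of dimension
#'   iterations x regions x methods, `test_cor` (squared-correlation
#'   variant), `skipped` iteration log, `cfg`.
#' @export
run_crossval <- function(Y_roi, cohort, cfg = cv_config(),
                         methods = c("global_scaling", "local_covariation")) {
  n_roi <- ncol(Y_roi)
  dims <- c(cfg$n_iterations, n_roi, length(methods))
  dn <- list(NULL, colnames(Y_roi) %||% seq_len(n_roi), methods)
  train <- array(NA_real_, dims, dimnames = dn)
  test <- array(NA_real_, dims, dimnames = dn)
  test_cor <- array(NA_real_, dims, dimnames = dn)
  skipped <- integer(0)
  for (it in seq_len(cfg$n_iterations)) {
    split <- split_half(cohort, cfg, it)
    res <- tryCatch(
      lapply(methods, function(m)
        cv_iteration(Y_roi, cohort, split, m,
                     test_centering = cfg$test_centering)),
      error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, it); next }
    for (k in seq_along(methods)) {
      train[it, , k] <- res[[k]]$train_r2
      test[it, , k] <- res[[k]]$test_r2
      test_cor[it, , k] <- res[[k]]$test_r2_cor
    }
  }
  structure(list(train = train, test = test, test_cor = test_cor,
                 skipped = skipped, cfg = cfg, methods = methods),
            class = "vbm_cv")
}

#' @export
print.vbm_cv <- function(x, ...) {
  cat(sprintf("Split-half cross-validation: %d iterations x %d ROIs x %s\n",
              dim(x$train)[1], dim(x$train)[2],
              paste(x$methods, collapse = " vs ")))
  if (length(x$skipped))
    cat(sprintf("  %d iterations skipped (singular designs)\n",
                length(x$skipped)))
  invisible(x)
}

#' Summarize a cross-validation run
#'
#' @param cv a `vbm_cv` result.
#' @return object of class `vbm_cv_summary`: `iteration_means` (data.frame
#'   of per-iteration ROI-mean R-squared, train and test, per method),
#'   `roi_medians` (per-ROI across-iteration medians), `wins` (per split,
#'   the number of ROIs where each method's median exceeds the other's),
#'   and histogram bin counts of the per-iteration means.
#' @export
summarize_cv <- function(cv) {
  stopifnot(inherits(cv, "vbm_cv"))
  ok <- setdiff(seq_len(dim(cv$train)[1]), cv$skipped)
  it_means <- do.call(rbind, lapply(seq_along(cv$methods), function(k) {
    data.frame(iteration = ok, method = cv$methods[k],
               train = rowMeans(cv$train[ok, , k, drop = FALSE]),
               test = rowMeans(cv$test[ok, , k, drop = FALSE]),
               row.names = NULL)
  }))
  roi_medians <- do.call(rbind, lapply(seq_along(cv$methods), function(k) {
    data.frame(roi = dimnames(cv$train)[[2]], method = cv$methods[k],
               train = apply(cv$train[ok, , k, drop = FALSE], 2, stats::median),
               test = apply(cv$test[ok, , k, drop = FALSE], 2, stats::median),
               row.names = NULL)
  }))
  wins <- list()
  if (length(cv$methods) == 2) {
    m1 <- roi_medians[roi_medians$method == cv$methods[1], ]
    m2 <- roi_medians[roi_medians$method == cv$methods[2], ]
    for (sp in c("train", "test")) {
      wins[[sp]] <- stats::setNames(
        c(sum(m1[[sp]] > m2[[sp]]), sum(m2[[sp]] > m1[[sp]])),
        cv$methods)
    }
  }
  hist_breaks <- seq(min(it_means$train, it_means$test),
                     max(it_means$train, it_means$test), length.out = 41)
  hists <- lapply(split(it_means, it_means$method), function(d)
    list(train = graphics::hist(d$train, breaks = hist_breaks, plot = FALSE)$counts,
         test = graphics::hist(d$test, breaks = hist_breaks, plot = FALSE)$counts,
         breaks = hist_breaks))
  structure(list(iteration_means = it_means, roi_medians = roi_medians,
                 wins = wins, histograms = hists, methods = cv$methods),
            class = "vbm_cv_summary")
}

#' @export
print.vbm_cv_summary <- function(x, ...) {
  for (m in x$methods) {
    d <- x$iteration_means[x$iteration_means$method == m, ]
    cat(sprintf("%-18s mean R2: train %.3f, test %.3f (over %d iterations)\n",
                m, mean(d$train), mean(d$test), nrow(d)))
  }
  if (length(x$wins)) {
    cat(sprintf("ROIs won on train: %s\n",
                paste(sprintf("%s %d", names(x$wins$train), x$wins$train),
                      collapse = ", ")))
    cat(sprintf("ROIs won on test:  %s\n",
                paste(sprintf("%s %d", names(x$wins$test), x$wins$test),
                      collapse = ", ")))
  }
  invisible(x)
}
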