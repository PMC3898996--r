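test_that("design construction produces the documented columns and centering", {
  coh <- generate_cohort(cohort_spec(seed = 1))
  coh$tgm <- rnorm(nrow(coh), 600, 30)
  d <- build_design(coh)
  expect_equal(d$roles, c("age_lin_M", "age_quad_M", "age_lin_F", "age_quad_F",
                          "const_M", "const_F", "tiv"))
  d8 <- build_design(coh, include_tgm = TRUE)
  expect_equal(ncol(d8$X), 8)
  expect_lt(abs(mean(d8$X[, "tgm"])), 1e-10)
  # per-sex age columns sum to zero within their sex
  for (cl in c("age_lin_M", "age_quad_M", "age_lin_F", "age_quad_F"))
    expect_lt(abs(sum(d8$X[, cl])), 1e-8)

  coh_m <- coh[coh$sex == "M", ]
  expect_warning(dm <- build_design(coh_m), "single-sex")
  expect_equal(dm$roles, c("age_lin_M", "age_quad_M", "const_M", "tiv"))

  coh_bad <- coh
  coh_bad$tiv <- 1500  # constant -> zero centered column
  expect_error(build_design(coh_bad), "collinear.*tiv")
})

test_that("OLS reproduces exact linear data and the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5)
  d <- toy_design(x)
  y <- 2 * (x - mean(x)) + 3
  fit <- fit_ols(matrix(y, 1), d)
  expect_equal(unname(fit$betas[, 1]), c(2, 3), tolerance = 1e-12)
  expect_equal(fit$sigma2[1], 0, tolerance = 1e-20)

  skip_if_not_installed("MASS")
  set.seed(2)
  for (i in 1:30) {
    n <- sample(6:20, 1); p <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", seq_len(p))
    design <- structure(list(X = X, roles = colnames(X), centering = list(),
                             sex_counts = NULL), class = "vbm_design")
    y <- rnorm(n)
    fit <- fit_ols(matrix(y, 1), design)
    expect_equal(unname(fit$betas[, 1]), ols_oracle(X, y), tolerance = 1e-10)
  }

  expect_error(fit_ols(matrix(c(1, NA, 3, 4, 5), 1), d), "non-finite")
})

test_that("the sex-weighted constant equals the per-unit mean (LGM identity)", {
  coh <- generate_cohort(cohort_spec(n_per_decade = 20, seed = 3))
  set.seed(3)
  Y <- matrix(rnorm(nrow(coh) * 50, mean = 0.5, sd = 0.2), nrow(coh))
  fit <- vbm_fit(pmax(Y, 0), coh, "none")
  expect_equal(fit$lgm, colMeans(pmax(Y, 0)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("contrast t and tail handling behave as specified", {
  # slope exactly zero: t = 0, one-tailed p = 0.5
  d <- toy_design(c(-1, 0, 1, -1, 0, 1))
  y <- c(1, 2, 1, 1, 2, 1)
  fit <- fit_ols(matrix(y, 1), d)
  ctr <- contrast_t(fit, c(x = 1), tail = "lower")
  expect_equal(ctr$p[1], 0.5, tolerance = 1e-12)
  expect_equal(ctr$effect[1], 0, tolerance = 1e-12)

  expect_error(contrast_t(fit, c(x = 1), tail = "sideways"))
  expect_error(contrast_t(fit, rep(1, 5)), "one entry per design column")

  # two-tailed p is twice the smaller one-tailed p
  set.seed(4)
  y2 <- rnorm(6)
  f2 <- fit_ols(matrix(y2, 1), d)
  lo <- contrast_t(f2, c(x = 1), "lower")$p
  up <- contrast_t(f2, c(x = 1), "upper")$p
  two <- contrast_t(f2, c(x = 1), "two")$p
  expect_equal(two, 2 * pmin(lo, up), tolerance = 1e-12)
})

test_that("null decline p-values are uniform (simulation)", {
  # 1000 independent null units at once; lower-tail p ~ U(0,1)
  coh <- generate_cohort(cohort_spec(n_per_decade = 10, seed = 5))
  set.seed(5)
  Y <- matrix(rnorm(nrow(coh) * 1000, mean = 0.5, sd = 0.1), nrow(coh))
  fit <- vbm_fit(Y, coh, "none")
  ks <- suppressWarnings(ks.test(fit$contrast$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("partial R2 matches its definition and guards nesting", {
  x <- seq(-2, 2, length.out = 9)
  d_full <- toy_design(x)
  d_red <- structure(list(X = d_full$X[, "const", drop = FALSE],
                          roles = "const", centering = list(),
                          sex_counts = NULL), class = "vbm_design")
  y_noiseless <- 3 * (x - mean(x)) + 1
  f_full <- fit_ols(matrix(y_noiseless, 1), d_full)
  f_red <- fit_ols(matrix(y_noiseless, 1), d_red)
  expect_equal(partial_r2(f_full, f_red)[1], 1)
  expect_equal(partial_r2(f_full, f_full)[1], 0)

  set.seed(6)
  y <- rnorm(9)
  f1 <- fit_ols(matrix(y, 1), d_full)
  f0 <- fit_ols(matrix(y, 1), d_red)
  # explicit RSS oracle
  rss1 <- sum(lm.fit(d_full$X, y)$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(partial_r2(f1, f0)[1], (rss0 - rss1) / rss0, tolerance = 1e-12)

  d_other <- structure(list(X = cbind(z = rnorm(9)), roles = "z",
                            centering = list(), sex_counts = NULL),
                       class = "vbm_design")
  f_other <- fit_ols(matrix(y, 1), d_other)
  expect_error(partial_r2(f1, f_other), "not nested")
})

test_that("FWE correction satisfies its basic contracts", {
  x <- seq(-2, 2, length.out = 12)
  d <- toy_design(x)
  set.seed(7)
  Y <- matrix(rnorm(12 * 100), 100, 12)
  fit <- fit_ols(Y, d)
  ctr <- contrast_t(fit, c(x = 1), "lower")

  b <- fwe_correct(ctr, method = "bonferroni")
  expect_true(all(b$p_fwe >= b$p))
  expect_equal(b$p_fwe, pmin(1, 100 * ctr$p), tolerance = 1e-12)

  one <- contrast_t(fit_ols(Y[1, , drop = FALSE], d), c(x = 1), "lower")
  expect_equal(fwe_correct(one, method = "bonferroni")$p_fwe, one$p)

  expect_error(fwe_correct(ctr, fit, "permutation_maxT", n_perm = 199),
               "seed")
  pm <- fwe_correct(ctr, fit, "permutation_maxT", n_perm = 199, seed = 1)
  expect_true(all(pm$p_fwe >= pm$p))
  expect_true(all(pm$p_fwe >= 1 / 200 & pm$p_fwe <= 1))
})

test_that("global trends recover noiseless polynomials and guard TIV", {
  coh <- generate_cohort(cohort_spec(n_per_decade = 15, seed = 8))
  expect_error(fit_global_trend(coh$tiv, coh, covary_tiv = TRUE),
               "covary_tiv = FALSE")

  ac <- coh$age - mean(coh$age)
  vals <- 700 - 0.8 * ac - 0.01 * (ac^2 - mean(ac^2))
  tr <- fit_global_trend(vals, coh, covary_tiv = FALSE)
  expect_equal(tr$linear$beta, -0.8, tolerance = 1e-10)
  expect_equal(tr$quadratic$beta, -0.01, tolerance = 1e-10)
  expect_equal(tr$age_partial_r2, 1, tolerance = 1e-10)
  # percent-change closed form from the fitted curve endpoints
  rng <- range(coh$age)
  f <- function(a) 700 - 0.8 * (a - mean(coh$age)) -
    0.01 * ((a - mean(coh$age))^2 - mean(ac^2))
  expect_equal(tr$percent_change, 100 * (f(rng[2]) - f(rng[1])) / f(rng[1]),
               tolerance = 1e-8)
})

test_that("synthetic TGM age trend is recovered within its confidence interval", {
  atl <- tiny_atlas()
  coh <- generate_cohort(cohort_spec(seed = 9))
  regs <- region_specs_default(atl, seed = 9)
  sim <- generate_gm_images(coh, regs, atl, tiny_spec(seed = 9, smoothing_fwhm = 0))
  # ground-truth TGM slope: sum over voxels of p_v * b_r x voxel volume
  lab <- as.integer(atl$labels)
  b_v <- ifelse(lab > 0, regs$linear_slope[match(lab, regs$label)], 0)
  truth <- sum(sim$ground_truth$p_v * b_v) * sim$unsmoothed$voxel_size^3 / 1000
  tr <- fit_global_trend(sim$cohort$tgm, sim$cohort, covary_tiv = FALSE)
  se <- abs(tr$linear$beta / qt(tr$linear$p_one_tailed, tr$df))
  expect_lt(abs(tr$linear$beta - truth), qt(0.975, tr$df) * se)
})

test_that("adding an orthogonal column leaves other coefficients unchanged", {
  set.seed(10)
  n <- 40
  X <- cbind(const = 1, x = as.numeric(scale(rnorm(n), scale = FALSE)))
  z <- rnorm(n)
  z <- residuals(lm.fit(X, z))  # orthogonal to both columns
  d1 <- structure(list(X = X, roles = colnames(X), centering = list(),
                       sex_counts = NULL), class = "vbm_design")
  X2 <- cbind(X, z = z)
  d2 <- structure(list(X = X2, roles = colnames(X2), centering = list(),
                       sex_counts = NULL), class = "vbm_design")
  y <- matrix(rnorm(3 * n), 3)
  f1 <- fit_ols(y, d1); f2 <- fit_ols(y, d2)
  expect_equal(f1$betas["x", ], f2$betas["x", ], tolerance = 1e-10)
  expect_equal(f1$betas["const", ], f2$betas["const", ], tolerance = 1e-10)
})
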