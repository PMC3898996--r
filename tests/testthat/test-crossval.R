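test_that("split-half partitions are deterministic, disjoint and balanced", {
  coh <- generate_cohort(cohort_spec(seed = 1))
  cfg <- cv_config(seed = 5)
  s1 <- split_half(coh, cfg, 7)
  s2 <- split_half(coh, cfg, 7)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 210)
  expect_equal(length(s1$test), 210)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), seq_len(420))
  expect_false(identical(split_half(coh, cfg, 8)$train, s1$train))

  cfgS <- cv_config(seed = 5, stratify = "by_sex_and_decade")
  sS <- split_half(coh, cfgS, 1)
  cell <- interaction(coh$sex, coh$decade)
  for (cl in levels(cell)) {
    n_tr <- sum(sS$train %in% which(cell == cl))
    n_cl <- sum(cell == cl)
    expect_lte(abs(n_tr - n_cl / 2), 0.5)
  }
  expect_error(split_half(coh[1:3, ], cfg, 1), "at least 4")
})

test_that("one CV iteration matches a hand-rolled oracle on a small instance", {
  # one small ROI; follow the two test-set equations step by step with lm()
  # (single-sex cohort so each 8-subject half supports the design)
  coh <- generate_cohort(cohort_spec(n_per_decade = 4, age_range = c(20, 60),
                                     sex_ratio = 1, seed = 2))
  expect_equal(nrow(coh), 16)
  set.seed(2)
  n <- nrow(coh)
  y <- 0.6 - 0.003 * (coh$age - mean(coh$age)) + rnorm(n, 0, 0.02)
  coh$tgm <- 600 + rnorm(n, 0, 20)
  coh$twm <- 500; coh$tcsf <- 300
  Y <- matrix(y, ncol = 1); colnames(Y) <- "r1"
  split <- list(train = seq(1, n, 2), test = seq(2, n, 2))

  for (method in c("global_scaling", "local_covariation")) {
    got <- suppressWarnings(cv_iteration(Y, coh, split, method))
    # ---- oracle
    tr <- split$train; te <- split$test
    d_tr <- suppressWarnings(
      build_design(coh[tr, ], include_tgm = (method == "local_covariation")))
    y_tr <- if (method == "global_scaling") y[tr] / coh$tgm[tr] else y[tr]
    b_tr <- qr.coef(qr(d_tr$X), y_tr)
    age_roles <- grep("^age_", d_tr$roles, value = TRUE)
    d_te <- suppressWarnings(
      build_design(coh[te, ], include_tgm = (method == "local_covariation"),
                   centering = d_tr$centering))
    Z <- d_te$X[, grep("^(const_|tiv$)", d_te$roles), drop = FALSE]
    if (method == "global_scaling") {
      y_adj <- y[te] / coh$tgm[te]
    } else {
      joint <- cbind(Z, tgm = d_te$X[, "tgm"])
      bj <- qr.coef(qr(joint), y[te])
      y_adj <- y[te] - d_te$X[, "tgm"] * bj["tgm"]
    }
    y_res <- y_adj - Z %*% qr.coef(qr(Z), y_adj)
    pred <- d_te$X[, age_roles, drop = FALSE] %*% b_tr[age_roles]
    pred <- pred - Z %*% qr.coef(qr(Z), pred)
    r2_o <- 1 - sum((y_res - pred)^2) / sum(y_res^2)
    expect_equal(got$test_r2, r2_o, tolerance = 1e-10)
  }
})

test_that("noiseless pure-age data generalize almost perfectly", {
  coh <- generate_cohort(cohort_spec(n_per_decade = 20, seed = 3))
  ac <- coh$age - mean(coh$age)
  Y <- matrix(0.6 - 0.003 * ac, ncol = 1)
  coh$tgm <- 650 + rnorm(nrow(coh), 0, 10)  # independent of age and data
  coh$twm <- 500; coh$tcsf <- 300
  split <- split_half(coh, cv_config(seed = 3), 1)
  got <- cv_iteration(Y, coh, split, "local_covariation")
  expect_gt(got$test_r2, 0.99)
  expect_gt(got$train_r2, 0.99)
})

test_that("age-free data have near-zero generalizable age variance", {
  coh <- generate_cohort(cohort_spec(n_per_decade = 25, seed = 4))
  set.seed(4)
  Y <- matrix(0.6 + rnorm(nrow(coh), 0, 0.05), ncol = 1)
  coh$tgm <- 650 + rnorm(nrow(coh), 0, 10)
  cv <- run_crossval(Y, coh, cv_config(n_iterations = 100, seed = 4))
  med <- apply(cv$test[, 1, , drop = TRUE], 2, median)
  expect_lt(max(abs(med)), 0.05)
})

test_that("full-data R2 separates the two generative regimes", {
  coh <- generate_cohort(cohort_spec(seed = 5))
  # purely proportional, noiseless: after scaling no age variance remains
  ac <- coh$age - mean(coh$age)
  G <- (1 - 0.001 * (coh$age - min(coh$age))) * exp(rnorm(420, 0, 0.05))
  m <- c(0.5, 0.7, 0.4)
  Yp <- outer(G, m)
  cohp <- coh; cohp$tgm <- rowSums(Yp)
  fd <- full_data_r2(Yp, cohp)
  expect_lt(max(fd$r2_global_scaling), 1e-10)

  # strong age effect, no global coupling, TGM pure noise: both methods
  # see close to the true age fraction of variance
  set.seed(5)
  b <- -0.003
  noise <- rnorm(420, 0, 0.03)
  Ya <- matrix(0.6 + b * ac + noise, ncol = 1)
  coha <- coh; coha$tgm <- 650 + rnorm(420, 0, 10)
  fda <- full_data_r2(Ya, coha)
  truth <- var(b * ac) / var(b * ac + noise)
  expect_equal(fda$r2_global_scaling, truth, tolerance = 0.1)
  expect_equal(fda$r2_local_covariation, truth, tolerance = 0.1)
})

test_that("method comparison is antisymmetric and overfits in the right direction", {
  coh <- generate_cohort(cohort_spec(n_per_decade = 20, seed = 6))
  dat <- roi_level_data(coh, m = runif(10, 0.4, 0.8),
                        b = runif(10, -3e-3, -5e-4),
                        lambda = runif(10, 0.005, 0.06), seed = 6)
  cfg <- cv_config(n_iterations = 150, seed = 6)
  cv_ab <- run_crossval(dat$Y, dat$cohort, cfg,
                        methods = c("global_scaling", "local_covariation"))
  cv_ba <- run_crossval(dat$Y, dat$cohort, cfg,
                        methods = c("local_covariation", "global_scaling"))
  sm_ab <- summarize_cv(cv_ab)
  sm_ba <- summarize_cv(cv_ba)
  expect_identical(unname(sm_ab$wins$test),
                   unname(rev(sm_ba$wins$test)))
  expect_identical(sm_ab$wins$test[["local_covariation"]],
                   sm_ba$wins$test[["local_covariation"]])
  # training R2 exceeds test R2 on average (overfitting direction)
  for (m in cv_ab$methods) {
    d <- sm_ab$iteration_means[sm_ab$iteration_means$method == m, ]
    expect_gt(mean(d$train), mean(d$test))
  }
})
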