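test_that("cohort generation honors the per-decade sampling design", {
  coh <- generate_cohort(cohort_spec(seed = 42))
  expect_equal(nrow(coh), 420)
  expect_equal(unname(table(coh$decade)), rep(70L, 6), ignore_attr = TRUE)
  expect_true(all(coh$age >= 18 & coh$age <= 77))
  within_band <- coh$age >= 18 + 10 * (coh$decade - 1) &
    coh$age <= pmin(18 + 10 * coh$decade, 77)
  expect_true(all(within_band))

  minimal <- generate_cohort(cohort_spec(n_per_decade = 1, seed = 1))
  expect_equal(nrow(minimal), 6)
  expect_equal(unname(table(minimal$decade)), rep(1L, 6), ignore_attr = TRUE)
})

test_that("generators are deterministic given their seed", {
  s <- cohort_spec(n_per_decade = 5, seed = 9)
  expect_identical(generate_cohort(s), generate_cohort(s))

  coh <- tiny_cohort(seed = 9)
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, seed = 9)
  spec <- tiny_spec(seed = 9, smoothing_fwhm = 0)
  a <- generate_gm_images(coh, regs, atl, spec)
  b <- generate_gm_images(coh, regs, atl, spec)
  expect_identical(a$unsmoothed$data, b$unsmoothed$data)
  expect_identical(a$ground_truth$g, b$ground_truth$g)

  d1 <- generate_fig1_dataset(seed = 3)
  d2 <- generate_fig1_dataset(seed = 3)
  expect_identical(d1, d2)
})

test_that("invalid specifications fail naming the offending field", {
  expect_error(cohort_spec(n_per_decade = 0), "n_per_decade")
  expect_error(cohort_spec(age_range = c(77, 18)), "age_range")
  expect_error(cohort_spec(sex_ratio = 1.5), "sex_ratio")
  expect_error(cohort_spec(tiv_sd = 0), "tiv_sd")
  expect_error(image_gen_spec(pv_floor = 0), "pv_floor")
  expect_error(image_gen_spec(noise_sd = -1), "noise_sd")
})

test_that("a region spec must exist for every atlas label", {
  coh <- tiny_cohort()
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, seed = 1)
  expect_error(
    generate_gm_images(coh, regs[regs$label > 3, ], atl, tiny_spec()),
    "labels without a region specification.*1")
})

test_that("noiseless uniform-profile images equal the linear model exactly", {
  coh <- tiny_cohort(seed = 2)
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, seed = 2)
  regs$quad_slope <- 0; regs$tiv_coef <- 0; regs$global_coef <- 0
  spec <- tiny_spec(seed = 2, noise_sd = 0, pv_profile = "uniform",
                    smoothing_fwhm = 0)
  sim <- generate_gm_images(coh, regs, atl, spec)
  lab <- as.integer(atl$labels)
  ac <- coh$age - mean(coh$age)
  for (l in c(1, 10, 18)) {
    r <- match(l, regs$label)
    expected <- regs$mean_gm[r] + regs$linear_slope[r] * ac
    vox <- which(lab == l)
    expect_equal(sim$unsmoothed$data[, vox],
                 matrix(expected, nrow(coh), length(vox)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("radial profile makes voxelwise age slopes proportional to p_v", {
  coh <- tiny_cohort(seed = 3)
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, seed = 3)
  regs$quad_slope <- 0; regs$tiv_coef <- 0; regs$global_coef <- 0
  spec <- tiny_spec(seed = 3, noise_sd = 0, pv_profile = "radial",
                    smoothing_fwhm = 0)
  sim <- generate_gm_images(coh, regs, atl, spec)
  # per-voxel OLS oracle on the noiseless data
  ac <- coh$age - mean(coh$age)
  X <- cbind(ac, 1)
  betas <- qr.coef(qr(X), sim$unsmoothed$data)[1, ]
  lab <- as.integer(atl$labels)
  p_v <- sim$ground_truth$p_v
  for (l in c(2, 7)) {
    r <- match(l, regs$label)
    vox <- which(lab == l)
    expect_equal(betas[vox], regs$linear_slope[r] * p_v[vox],
                 tolerance = 1e-8, ignore_attr = TRUE)
    # |slope| is largest at the region centre, where p_v = 1
    expect_equal(which.max(abs(betas[vox])), which.max(p_v[vox]))
  }
})

test_that("a designed 2:1 slope ratio between regions is recovered at n = 420", {
  coh <- generate_cohort(cohort_spec(seed = 4))
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, seed = 4)
  regs$linear_slope <- rep(0, nrow(regs))
  regs$linear_slope[regs$label == 1] <- -0.004
  regs$linear_slope[regs$label == 2] <- -0.002
  regs$quad_slope <- 0
  spec <- tiny_spec(seed = 4, noise_sd = 0.02, pv_profile = "uniform",
                    smoothing_fwhm = 0)
  sim <- generate_gm_images(coh, regs, atl, spec)
  Yroi <- roi_means(sim$unsmoothed, atl)
  fit <- vbm_fit(Yroi, sim$cohort, "none")
  slopes <- fit$contrast$effect
  expect_equal(slopes[["1"]] / slopes[["2"]], 2, tolerance = 0.1)
})

test_that("image totals are conserved and clipping stays below 1% at defaults", {
  coh <- tiny_cohort(seed = 5)
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, seed = 5)
  sim <- generate_gm_images(coh, regs, atl, tiny_spec(seed = 5))
  tot <- unname(compute_tissue_totals(sim$unsmoothed))
  expect_equal(tot, sim$cohort$tgm, tolerance = 1e-8)
  expect_lt(sim$ground_truth$clip_rate, 0.01)
  expect_equal(compute_tiv(sim$cohort$tgm, sim$cohort$twm, sim$cohort$tcsf),
               sim$cohort$tiv, tolerance = 1e-10)
})

test_that("ROI-level OLS recovers generative slopes at nominal CI coverage", {
  # 50 replicated cohorts' images; each region's 95% CI should cover the
  # ground-truth ROI slope (generative slope x mean partial volume) at
  # close to nominal rate
  atl <- synthetic_atlas(grid_shape = c(12, 12, 24), block = 4,
                         n_per_hemisphere = 12)
  coh <- generate_cohort(cohort_spec(seed = 6))
  regs <- region_specs_default(atl, seed = 6)
  lab <- as.integer(atl$labels)
  cover <- 0L; total <- 0L
  for (rep in 1:50) {
    sim <- generate_gm_images(coh, regs, atl,
      image_gen_spec(grid_shape = c(12, 12, 24), seed = 600 + rep,
                     smoothing_fwhm = 0))
    Yroi <- roi_means(sim$unsmoothed, atl)
    fit <- vbm_fit(Yroi, sim$cohort, "none")
    pv <- sim$ground_truth$p_v
    truth <- vapply(atl$table$label, function(l)
      regs$linear_slope[match(l, regs$label)] * mean(pv[lab == l]), 0)
    w <- age_linear_weights(fit)
    se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$xtx_inv %*% w))
    est <- fit$contrast$effect
    half <- qt(0.975, fit$df) * se
    cover <- cover + sum(truth >= est - half & truth <= est + half)
    total <- total + length(truth)
  }
  expect_gte(cover / total, 0.93)
})

test_that("proportional data behave as a Global Scaling null", {
  coh <- generate_cohort(cohort_spec(seed = 7))
  atl <- tiny_atlas()
  regs <- region_specs_default(atl, coupling = "proportional", seed = 7)
  # noiseless: scaling removes the age effect exactly
  sim0 <- generate_proportional_dataset(coh, regs, atl,
    tiny_spec(seed = 7, noise_sd = 0, smoothing_fwhm = 0),
    subject_noise_sd = 0.05)
  Yroi0 <- roi_means(sim0$unsmoothed, atl)
  fit_gs <- vbm_fit(Yroi0, sim0$cohort, "global_scaling")
  expect_lt(max(abs(fit_gs$contrast$effect)), 1e-10)
  # the unadjusted fit on the same data sees the global decline
  fit_none <- vbm_fit(Yroi0, sim0$cohort, "none")
  expect_true(all(fit_none$contrast$effect < 0))
  # Local Covariation also absorbs the global level (slopes shrink by
  # orders of magnitude relative to the unadjusted global decline)
  fit_lc <- vbm_fit(Yroi0, sim0$cohort, "local_covariation")
  expect_lt(max(abs(fit_lc$contrast$effect)),
            0.01 * max(abs(fit_none$contrast$effect)))
})

test_that("the shipped toy dataset reproduces the four-panel pattern", {
  # expected values frozen from an independent lm() oracle run on the
  # shipped defaults
  tab <- fig1_demo()
  none <- tab[tab$mode == "none", ]
  expect_equal(none$slope, c(-0.020781327, -0.009385335), tolerance = 1e-6)
  expect_true(all(none$p_one_tailed < 0.05))
  expect_equal(none$slope[1] / none$slope[2], 2, tolerance = 0.15)

  gs <- tab[tab$mode == "global_scaling", ]
  expect_true(all(gs$p_one_tailed > 0.05))

  lc <- tab[tab$mode == "local_covariation", ]
  expect_lt(lc$slope[1], 0)
  expect_gt(lc$slope[2], 0)

  ls <- tab[tab$mode == "local_scaling", ]
  expect_true(all(ls$slope < 0))
  expect_lt(abs(ls$slope[1] - ls$slope[2]) / abs(ls$slope[1]), 0.10)
  # Local Scaling carries the unadjusted statistics over unchanged
  expect_identical(ls$p_one_tailed, none$p_one_tailed)
})

test_that("toy dataset fits match an independent lm() oracle", {
  d <- generate_fig1_dataset(seed = 77)
  ac <- d$age - mean(d$age)
  tab <- fig1_demo(d)
  for (r in 1:2) {
    y <- d[[paste0("region", r, "_gm")]]
    m <- lm(y ~ ac)
    row <- tab[tab$mode == "none" & tab$region == r, ]
    expect_equal(row$slope, unname(coef(m)["ac"]), tolerance = 1e-10)
    expect_equal(row$r2, summary(m)$r.squared, tolerance = 1e-10)
    mlc <- lm(y ~ ac + I(d$tgm - mean(d$tgm)))
    rowlc <- tab[tab$mode == "local_covariation" & tab$region == r, ]
    expect_equal(rowlc$slope, unname(coef(mlc)["ac"]), tolerance = 1e-10)
  }
})
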