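# Small fixtures shared across tests; everything is generated in code.

tiny_atlas <- function(grid = c(12, 12, 12), block = 4, nph = 9) {
  synthetic_atlas(grid_shape = grid, block = block, n_per_hemisphere = nph)
}

tiny_cohort <- function(n_per_decade = 8, seed = 1, ...) {
  generate_cohort(cohort_spec(n_per_decade = n_per_decade, seed = seed, ...))
}

tiny_spec <- function(grid = c(12, 12, 12), seed = 1, ...) {
  image_gen_spec(grid_shape = grid, seed = seed, ...)
}

# A hand-built minimal design for engine-level tests that do not need the
# cohort route: columns x (centered) and const.
toy_design <- function(x) {
  X <- cbind(x = x - mean(x), const = 1)
  structure(list(X = X, roles = colnames(X),
                 centering = list(), sex_counts = NULL),
            class = "vbm_design")
}

# Independent normal-equations oracle (pseudo-inverse route).
ols_oracle <- function(X, y) {
  drop(MASS::ginv(crossprod(X)) %*% crossprod(X, y))
}

# ROI-level synthetic data built directly (no images): subjects x regions,
# y_ir = m_r + b_r * (age - mean) + lambda_r * g_i + noise. Returns the
# cohort with tgm filled from the summed regions.
roi_level_data <- function(cohort, m, b, lambda, noise_sd = 0.02, seed = 1,
                           region_vol = 1) {
  set.seed(seed)
  n <- nrow(cohort)
  ac <- cohort$age - mean(cohort$age)
  g <- rnorm(n)
  Y <- outer(rep(1, n), m) + outer(ac, b) + outer(g, lambda) +
    matrix(rnorm(n * length(m), sd = noise_sd), n)
  cohort$tgm <- rowSums(Y) * region_vol
  rem <- pmax(cohort$tiv - cohort$tgm, 0)
  cohort$twm <- 0.6 * rem; cohort$tcsf <- 0.4 * rem
  colnames(Y) <- seq_along(m)
  list(Y = Y, cohort = cohort, g = g)
}
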