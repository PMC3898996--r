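#' Specify a synthetic cohort
#'
#' A cohort specification mirrors the sampling design of a large lifespan
#' structural-MRI study: a fixed number of participants per decade of age,
#' both sexes, and per-sex total intracranial volume (TIV) distributions.
#'
#' @param n_per_decade participants recruited in each decade band (default 70,
#'   giving 420 subjects over six decades at the default age range).
#' @param age_range numeric length-2, inclusive age range in years (default
#'   `c(18, 77)`); decade bands are consecutive 10-year intervals starting at
#'   `age_range[1]` (the last band is truncated at `age_range[2]`).
#' @param sex_ratio fraction of males in each decade band.
#' @param tiv_mean_by_sex named numeric, mean TIV in mL for `M` and `F`.
#'   Defaults reflect the well-replicated ~10% male-female head-size
#'   difference.
#' @param tiv_sd TIV standard deviation in mL (common to both sexes).
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_decade = 70,
                        age_range = c(18, 77),
                        sex_ratio = 0.5,
                        tiv_mean_by_sex = c(M = 1550, F = 1400),
                        tiv_sd = 110,
                        seed = 1L) {
  if (!is.numeric(n_per_decade) || length(n_per_decade) != 1L || n_per_decade < 1)
    stop_config("n_per_decade", "must be a single count >= 1")
  if (!is.numeric(age_range) || length(age_range) != 2L || age_range[1] >= age_range[2])
    stop_config("age_range", "must be an increasing [min, max] pair")
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop_config("sex_ratio", "must lie in [0, 1]")
  if (!all(c("M", "F") %in% names(tiv_mean_by_sex)))
    stop_config("tiv_mean_by_sex", "must name means for 'M' and 'F'")
  if (!is.numeric(tiv_sd) || tiv_sd <= 0)
    stop_config("tiv_sd", "must be > 0")
  structure(list(n_per_decade = as.integer(n_per_decade),
                 age_range = as.numeric(age_range),
                 sex_ratio = sex_ratio,
                 tiv_mean_by_sex = tiv_mean_by_sex,
                 tiv_sd = tiv_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws one subject row per participant: continuous age (uniform within each
#' decade band, avoiding the ties that integer ages would create), sex
#' assigned by `sex_ratio` within each band, and TIV drawn from the per-sex
#' normal distribution. Total tissue volumes (`tgm`, `twm`, `tcsf`) are left
#' `NA` until images are generated; they are filled in by
#' [generate_gm_images()] so that `tgm` is the integral of the subject's own
#' unsmoothed gray-matter image.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `gm_cohort` with columns `subject_id`,
#'   `age`, `sex`, `decade`, `tiv`, `tgm`, `twm`, `tcsf`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_decade = 2, seed = 7))
#' table(coh$decade)
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  starts <- seq(lo, hi, by = 10)
  starts <- starts[starts < hi]
  rows <- lapply(seq_along(starts), function(d) {
    a0 <- starts[d]; a1 <- min(a0 + 10, hi)
    n <- spec$n_per_decade
    n_m <- round(n * spec$sex_ratio)
    sex <- rep(c("M", "F"), c(n_m, n - n_m))
    data.frame(age = sort(stats::runif(n, a0, a1)),
               sex = sample(sex),
               decade = d)
  })
  coh <- do.call(rbind, rows)
  coh$tiv <- stats::rnorm(nrow(coh),
                          mean = spec$tiv_mean_by_sex[coh$sex],
                          sd = spec$tiv_sd)
  coh <- data.frame(subject_id = sprintf("sub-%04d", seq_len(nrow(coh))),
                    age = coh$age, sex = coh$sex, decade = coh$decade,
                    tiv = coh$tiv, tgm = NA_real_, twm = NA_real_,
                    tcsf = NA_real_)
  class(coh) <- c("gm_cohort", "data.frame")
  coh
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, ages %.1f-%.1f (%d M / %d F)\n",
              nrow(x), min(x$age), max(x$age),
              sum(x$sex == "M"), sum(x$sex == "F")))
  if (!all(is.na(x$tgm)))
    cat(sprintf("  TGM %.2f-%.2f mL, TIV %.0f-%.0f mL\n",
                min(x$tgm), max(x$tgm), min(x$tiv), max(x$tiv)))
  invisible(x)
}

#' Read / write cohort tables
#'
#' Cohort tables are exchanged as plain TSV with columns `subject_id`, `age`,
#' `sex`, `tiv`, `tgm`, `twm`, `tcsf`.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns a `gm_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  coh <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(coh) <- c("gm_cohort", "data.frame")
  coh
}
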