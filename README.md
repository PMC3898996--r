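# vbmadjust

Global-adjustment strategies for voxel-based morphometry (VBM) of
age-related gray-matter decline.

## The problem

Voxel-based morphometry fits a linear model to every voxel of a stack of
modulated, spatially normalized gray-matter (GM) images, asking where local
gray-matter volume (GMV) changes with age. Because *total* gray matter
(TGM) itself declines with age, the answer at any voxel depends on how the
analysis treats that global trend — and the literature disagrees on how to
do it. `vbmadjust` implements the four standard treatments as one
comparable suite, together with the diagnostics that distinguish them:

Given GMV `y_ir` for subject *i* at voxel/region *r*, age `a_i`, and
`t_i = TGM`, the suite fits

* **no adjustment** — `y_ir = β_r(a) a_i + β_r(c) + ε_ir`
* **Global Scaling** — `y_ir / t_i = β_r(a) a_i + β_r(c) + ε_ir`
  (proportional adjustment)
* **Local Covariation** — `y_ir = β_r(a) a_i + β_r(c) + β_r(t) t_i + ε_ir`
  (additive, voxel-specific adjustment)
* **Local Scaling** — the unadjusted fit, with the slope map re-expressed
  as `β_r(l) = β_r(a) / β_r(c)`, i.e. decline per unit of local mean GM
  (LGM); test statistics are unchanged.

The full models expand age to a second-degree polynomial separately for
each sex and always include total intracranial volume (TIV) as a covariate
of no interest. With the package's mean-centered design the constant term
equals the local mean GM, which makes Local Scaling and the slope-vs-LGM
diagnostics well defined.

Around that core the package provides:

* a synthetic-data generator producing cohorts, modulated GM image stacks
  (NIfTI-1), a 116-region bilateral atlas, and a two-region toy dataset,
  each with known ground truth — so every stage is testable without an MRI
  cohort;
* image operations: tissue totals and TIV, exactly mass-preserving
  separable Gaussian smoothing, analysis-mask creation;
* mass-univariate OLS with contrasts, one-tailed decline p-values, partial
  R², and familywise-error control (Bonferroni or Freedman–Lane max-T
  permutation);
* ROI aggregation, ranking by mean linear age effect, Kendall
  rank-concordance between adjustment modes, and Lilliefors/KS normality
  checks;
* the voxelwise correlation between local mean GM and the linear age slope,
  before and after Local Scaling (a partial-volume coupling diagnostic);
* split-half cross-validation of how well age effects estimated under
  Global Scaling vs Local Covariation generalize to held-out subjects.

## Worked example

```r
library(vbmadjust)

atlas   <- synthetic_atlas()                       # 116 regions, 24^3 grid
cohort  <- generate_cohort(cohort_spec(seed = 1))  # 420 subjects, 70/decade
regions <- region_specs_default(atlas, coupling = "heterogeneous", seed = 1)
sim     <- generate_gm_images(cohort, regions, atlas, image_gen_spec(seed = 1))

mask <- make_mask(sim$smoothed, threshold = 0.1)
fit  <- vbm_fit(sim$smoothed, sim$cohort, adjustment = "none", mask = mask)
summary(fit)
#> VBM analysis, adjustment = none
#>   420 subjects, 13824 units, df = 413
#>   sex-averaged linear slope range: [-0.0006979, -8.849e-05] per year
#>   decline: 13824 units p < .05 uncorrected; 12593 at Bonferroni FWE 0.05

slope_vs_lgm(fit)
#> Slope-LGM coupling over 13824 voxels (0 excluded):
#>   raw: Pearson r = -0.600 (p = 0)
#>   after Local Scaling: r = -0.013 (p = 0.121)
#>   mean relative error of the LGM estimate: 0.31%
```

Voxels with more gray matter decline faster (r < 0); dividing the slope
map by the mean-GM map (Local Scaling) removes most, but not all, of that
dependence. The toy two-region dataset shows how strongly the adjustment
choice drives conclusions:

```r
fig1_demo()
#>                 mode region         slope p_one_tailed        r2
#> 1               none      1 -0.0207813268 9.572850e-05 0.9774901
#> 2               none      2 -0.0093853349 1.739046e-03 0.9052618
#> 3     global_scaling      1 -0.0001155430 1.443747e-01 0.2718804
#> 4     global_scaling      2  0.0001155430 1.443747e-01 0.2718804
#> 5  local_covariation      1 -0.0054029961 2.037262e-02 0.9993486
#> 6  local_covariation      2  0.0054029961 2.037262e-02 0.9970441
#> 7      local_scaling      1 -0.0051971381 9.572850e-05 0.9774901
#> 8      local_scaling      2 -0.0047194109 1.739046e-03 0.9052618
```

Identical data: both regions decline (no adjustment); nothing is
significant (Global Scaling); the slower region *increases* relative to
the global trend (Local Covariation); and both regions decline at nearly
the same relative rate (Local Scaling).

The whole analysis — simulation, global trends, mask, the four fits, ROI
ranking, LGM coupling, cross-validation, toy demo — runs end to end with
`run_pipeline(list(out_dir = "vbm_run", seed = 1))`, which writes every
artifact plus a checksummed manifest, or from the shell via
`Rscript inst/scripts/vbm-pipeline.R --seed 1 --out vbm_run`.

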