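---
title: "Global adjustment in voxel-based morphometry: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global adjustment in voxel-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vbmadjust` studies a single methodological question in structural brain
imaging: when a mass-univariate analysis of modulated gray-matter (GM)
images asks where gray-matter volume changes with age, how should it treat
the fact that *total* gray matter (TGM) changes with age too? This
vignette documents the statistical models, what the synthetic-data
generator does and does not emulate, and the numerical decisions baked
into the implementation.

## The model

Every analysis fits, per voxel or region `r`, an ordinary-least-squares
model to `n` subjects. The full design contains

* per-sex linear and quadratic age terms (`age_lin_M`, `age_quad_M`,
  `age_lin_F`, `age_quad_F`), each zero for subjects of the other sex;
* per-sex constants (`const_M`, `const_F`);
* mean-centered total intracranial volume (TIV, mL), always included as a
  covariate of no interest;
* mean-centered TGM (mL), only under Local Covariation.

Sex-partitioned age columns let the two sexes have different age
trajectories; the reported "aging" effect is the sex-averaged linear slope
(weights 1/2, 1/2), tested one-tailed on the lower tail ("decline" means a
negative slope). One-tailed p-values elsewhere (global trends, the toy
table) are taken on the tail of the observed sign.

**Centering.** Age columns are centered *within sex*, and quadratic
columns are centered so they sum to zero within sex. Under this centering
every non-constant column is orthogonal to the constant direction, so the
sex-weighted average of the two constants equals the per-unit mean of the
data across all subjects — the local gray matter (LGM). This identity is
what makes Local Scaling (dividing the slope map by the constant map)
interpretable as "decline per unit of local mean GM", and it is enforced
to 1e-10 in the tests. TIV is also mean-centered; the field convention for
whether TIV is centered in such models is not settled, and centering is
chosen here for interpretability of the constants. Centering means are
recorded in the design so a held-out half can be projected through a
training half's centering.

**The four adjustments.**

* *None*: raw data, no TGM term.
* *Global Scaling*: each subject's image is divided by that subject's TGM
  before fitting. Scaled values are then multiplied by the cohort-mean TGM
  so they remain in GM density units; this grand-mean scaling affects
  parameter magnitudes only, never t or p (tested). Whether to re-multiply
  is a convention that differs between analysis packages; the choice here
  is explicit.
* *Local Covariation*: TGM enters the model as a per-unit regressor, so
  the global trend is removed additively with a voxel-specific
  coefficient.
* *Local Scaling*: the unadjusted fit's sex-averaged slope divided by the
  sex-weighted constant, in units of fraction of local mean GM per year.
  It is a descriptive rescaling: t and p are carried over bit-identically
  from the unadjusted fit. Units whose |constant| falls below a floor of
  1e-3 density units are excluded from the scaled map (division blow-up in
  near-empty voxels) and reported.

**Inference.** Familywise error over the voxel family is controlled by
Bonferroni (deterministic default) or by Freedman–Lane max-T permutation:
the nuisance-only model is fitted, its residuals permuted over subjects,
the full model refitted, and the most extreme contrast statistic per
permutation forms the null. Permutation p-values live on the grid
`1/(n_perm+1), ..., 1`, and corrected p-values are never allowed below
uncorrected ones. Random-field-theory correction is deliberately out of
scope; both implemented alternatives control familywise error validly,
which the suite verifies by simulation against a binomial bound.

**Global trends.** TIV, TGM, TWM and TCSF are modeled per subject as a
centered second-degree polynomial of age pooled across sexes, optionally
after covarying TIV (refused when the response *is* TIV). The fit reports
per-term estimates, one-tailed p, partial R², and the percent change of
the fitted curve between the age-range endpoints.

## What the synthetic generator emulates

No imaging cohort ships with the package; the generator produces the
*output* of a modulated VBM preprocessing chain with known ground truth.
Defaults encode the study conditions the analyses assume: 420 subjects, 70
per decade from 18–77 years, continuous ages sampled uniformly within each
decade band (the band counts are the design; a uniform within-band draw
avoids age ties without asserting more than the design states), both
sexes, and per-sex TIV (means 1550/1400 mL, SD 110 mL — the familiar ~10%
male–female head-size difference).

A voxel `v` of region `r` takes the value

```
y_iv = p_v [ m_r + b_r (a_i - mean a) + q_r (a_i - mean a)^2
             + h_r (TIV_i - mean TIV) + lambda_r g_i ] + eps_iv
```

clipped at zero, with `g_i ~ N(0,1)` a global individual factor shared by
all regions and `eps_iv ~ N(0, 0.05^2)` voxel noise. Defaults per region:
mean GM `m_r ~ U(0.4, 0.8)`; fractional decline `b_r / m_r` between 0.02%
and 0.25% per year (regions lose roughly 1–15% of their GM across the age
range, and the cohort-level TGM loss lands in the single-digit percent
range a lifespan sample shows); a small negative quadratic term; TIV
coupling proportional to `m_r`. The global-factor loading `lambda_r` comes
in two regimes: proportional to `m_r` (Global Scaling's generative regime)
or drawn independently of `m_r` (Local Covariation's regime) — each
adjustment method has a regime in which it is the correct model, and the
cross-validation comparison is run in both.

`p_v` is a within-region partial-volume profile: 1 at the region centroid
falling linearly to 0.5 at the edge (`radial`), or uniformly 1. The radial
profile is the minimal mechanism that couples a voxel's mean GM to the
magnitude of its age slope — the coupling the slope-vs-LGM diagnostic
measures — because both scale with `p_v` within a region. After Local
Scaling that common factor cancels, so the scaled correlation collapses
toward the between-region component only.

A second generator produces *purely proportional* data,
`y_iv = p_v m_r G(a_i) u_i + eps_iv` with `G` declining 0.1%/year and
multiplicative log-normal subject noise — the null model under which
Global Scaling removes all age structure (verified exactly in the
noiseless case).

The two-region toy dataset (six subjects at ages 30/60/90) is constructed
so the four adjustments reach their four qualitatively different
conclusions from identical data: slopes are proportional to region means
(hence Global Scaling nulls both and Local Scaling equalizes them, to
within noise), the shared global deviation loads equally on both regions
(hence Local Covariation flips the slower region positive), and the global
deviation is orthogonalized to age inside the generator so that, at n = 6,
the pattern is not hostage to one lucky draw. The shipped defaults were
fixed once against a plain `lm()` oracle and are frozen as a regression
fixture.

**What the generator does not emulate:** raw T1 intensities, segmentation
error, registration warps and their Jacobians, spatial autocorrelation of
noise (voxel noise is independent before smoothing), non-Gaussian
between-subject variation, or realistic anatomy (the atlas is a bilateral
block parcellation with AAL-like cardinality — 116 regions, 58 per
hemisphere — not anatomical shapes). Passing tests therefore demonstrate
that the *statistical machinery* behaves as specified under the stated
generative assumptions, not that any particular real-data preprocessing is
accurate. Totals are in toy units: a 24³ grid of 1.5 mm voxels holds a few
mL of "gray matter", not a brain's 600 mL; TIV stays at realistic mL scale
since only its variation enters the models.

## Image operations

Tissue totals integrate a subject's map over voxels times voxel volume
(mm³ → mL); TIV = TGM + TWM + TCSF. Totals are computed from *unsmoothed*
images, the synthetic analogue of native-space segmentations. Smoothing is
separable Gaussian with sigma = FWHM / (2√(2 ln 2)) / voxel size and
half-sample mirror boundary handling, under which every column of the 1-D
operator sums to one, so image totals are preserved exactly (the common
zero-padding alternative leaks mass at the edges; the difference is
negligible in the interior and documented here because it changes
edge-voxel values). The analysis mask is the across-subject mean of the
smoothed images thresholded at 0.1 — interpreted as modulated GM density,
unitless — and the same mask is used for every adjustment mode so that
modes are compared on identical voxels.

## ROI analysis and ranking

Two aggregation routes exist deliberately: ranking averages the voxelwise
*parameter estimates* within each region (the sex-averaged slope map, or
the Local-Scaled map for that mode), while per-ROI age trajectories
*refit* the models on ROI-mean data. Rankings sort ascending (rank 1 =
fastest decline), break ties by atlas label order (recorded), and report
Kendall's tau between modes — rank agreement across modes is an empirical
finding, never an assumption. Normality of ROI data and residuals is
checked with the Lilliefors-corrected Kolmogorov–Smirnov test
(`nortest::lillie.test`, the established implementation of the
estimated-parameters correction); constant input is reported as p = 0 with
a flag rather than an error.

## Split-half cross-validation

Each iteration draws a random half (210/210 at default size; optionally
stratified by sex × decade, with the odd subject of odd cells alternating
between halves), fits each method's model on the training half, and keeps
only the linear and quadratic age estimates. The test half is adjusted by
*its own* TGM — divided by it (Global Scaling) or with the fit of the test
TGM, re-estimated on the test half jointly with the test nuisance,
subtracted (Local Covariation) — then the test nuisance (constants, TIV)
is residualized out and the data are predicted by the training age terms.
Numerical choices:

* test-half age columns are centred with the *training* means by default
  (honest generalization; `test_centering = "test"` is available and
  recorded);
* the prediction is projected into the same nuisance-orthogonal subspace
  as the data, so nuisance handling cancels from the score; with noiseless
  data and exactly recovered age effects the test R² is exactly 1, and a
  zero age estimate scores exactly 0;
* R² = 1 − RSS/TSS by definition; it may be negative on the test half and
  is retained unclipped so medians are unbiased (a squared-correlation
  variant is also reported);
* singular test designs (e.g. a sex missing from a half) skip the
  iteration and are logged.

Default 1,000 iterations: the summaries are per-ROI medians and
per-iteration means, which stabilize well below 10,000 iterations — the
acceptance checks run the full comparison at 1,000 and the win counts are
stable across independent split seeds.

## Problem sizes and determinism

The shipped checks run at desk scale chosen to keep the full suite fast
while preserving the study conditions: 420 subjects on a 24³ grid (116
regions) for the main analyses, a 12³ grid for permutation-FWE simulation
(500 nulls × 199 permutations), 100 proportional-null replicates, 50
slope-LGM replicates, and 1,000 cross-validation iterations per regime.
Every stochastic stage takes a child seed derived from one master seed by
a fixed affine hash (`child_seed`), so a pipeline run is reproducible
artifact-for-artifact (checksummed manifests are compared in the tests)
while stages remain independently re-runnable.

## Known limitations

* The generator's noise is spatially independent before smoothing;
  permutation and Bonferroni FWE are exercised under exchangeability that
  real data only approximate.
* The atlas is geometric; conclusions about specific anatomical structures
  are out of reach by design.
* Global Scaling of near-zero TGM is undefined; nonpositive TGM is an
  error, not a warning.
* Single-sex cohorts drop the absent sex's columns with a warning; the
  "sex-averaged" contrast then degenerates to the single sex's slope.
* No random-field theory, cluster-extent inference, robust or
  mixed-effects variants; the suite is deliberately OLS end to end.
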