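Package: vbmadjust
Title: Global-Adjustment Strategies for Voxel-Based Morphometry of Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the treatment of global gray matter
    affects regionally-specific estimates of age-related gray-matter decline
    in voxel-based morphometry (VBM). Implements mass-univariate ordinary
    least squares with a per-sex polynomial age expansion and total
    intracranial volume as a covariate, four adjustments for total gray
    matter (none, Global Scaling, Local Covariation, Local Scaling),
    atlas-based region-of-interest aggregation and ranking, quantification
    of the coupling between local mean gray matter and age slopes, and
    split-half cross-validation of how well Global Scaling and Local
    Covariation generalize to held-out subjects. A synthetic-data generator
    produces modulated gray-matter image stacks, cohort tables and a
    two-region toy dataset with the statistical structure these analyses
    assume, so the whole pipeline is testable without access to an MRI
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
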