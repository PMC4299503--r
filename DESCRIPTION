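Package: agrimeta
Title: Hierarchical Meta-Analysis of Organic Farming Effects on Species Richness
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for hierarchical meta-analysis of paired organic versus
    conventional farming biodiversity comparisons. Computes log response-ratio
    effect sizes with normal-approximation adequacy diagnostics, fits a
    hierarchical Bayes linear meta-regression that models dependence among
    effect sizes from the same publication, and reports credible intervals,
    between-study heterogeneity (tau-squared, I-squared) and residual
    diagnostics. Includes publication-bias assessments (trim-and-fill,
    cumulative meta-analysis, sampling-variance and publication-year slope
    tests), a randomized 1-km transect sampler for land-use intensity metrics
    on categorical land-cover rasters, and a synthetic-data generator with
    known ground truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
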