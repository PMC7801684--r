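Package: dipterocarpSDM
Title: Species Distribution Models, Land-Cover Correction and Climate
    Macrorefugia for Philippine Dipterocarps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A presence-background species distribution modelling workflow for
    tropical tree species: maximum-entropy (Gibbs) models with lasso-penalized
    linear, quadratic, product and hinge features fitted by cyclic coordinate
    descent; species-specific background-extent calibration by Michaelis-Menten
    saturation of cross-validated AUC over distance buffers; spatial block and
    jackknife cross-validation with omission-rate model selection over a
    feature-class by regularization-multiplier grid; maxSSS binarization;
    post-hoc land-cover correction of projections; and climate-change range
    analytics (loss/stable/gain macrorefugia, richness stacking, protected-area
    coverage, elevation-shift profiles). Includes a synthetic-landscape
    generator (correlated environmental fields, species with known suitability,
    biased sampling, land cover, protected areas, future climates) so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
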