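Package: rspfrisk
Title: Resource Selection Probability Functions for Wildlife Conflict Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A use-availability modelling pipeline for mapping human-wildlife
    conflict risk from reported conflict locations and environmental raster
    covariates. Provides lightweight planar raster containers with
    distance-to-feature, reclassification, log-transform, resampling and
    point-extraction operations; randomized spatial thinning and
    buffer-excluded background point generation; maximum-likelihood
    estimation of logistic resource selection probability functions (RSPFs)
    under the weighted-distributions use-availability likelihood with
    nonparametric bootstrap standard errors; collinearity screening (VIF and
    pairwise correlation) and exhaustive all-subsets AIC model selection with
    a delta-AIC parsimony rule; ROC/AUC validation with
    equal-sensitivity-specificity thresholds, omission errors, spatial
    hold-out and stratified k-fold cross-validation; and projection of a
    fitted model across a covariate stack into a conflict-probability
    surface. A synthetic-landscape generator with a known true RSPF supports
    end-to-end testing against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
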