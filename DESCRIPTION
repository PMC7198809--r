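Package: voxsvm
Title: Voxel-Wise Linear SVM Classification of White-Matter Diffusion Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multivariate pattern analysis of registered scalar diffusion-metric
    volumes (typically fractional anisotropy maps) for two-group discrimination.
    Features are voxel values inside a white-matter analysis mask, ranked per
    training split by the Fisher score, and classified with a soft-margin linear
    support vector machine (C = 1) inside a nested leave-one-out cross-validation
    over a grid of feature-set sizes. Inference uses label-permutation tests, ROC
    analysis of the decision values, and Spearman correlation of decision values
    with clinical severity scores. The per-fold weight vectors are averaged and
    back-projected into a discriminative brain map that is thresholded per sign
    and reported as connected clusters. A synthetic-cohort generator produces
    FA-like volumes with planted group effects so the whole pipeline can be
    exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC
Config/testthat/edition: 3
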