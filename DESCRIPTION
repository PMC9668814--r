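Package: braintex
Title: Voxel-Wise GLCM Texture Maps and Explainable MLP Classification for Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise three-dimensional gray-level co-occurrence
    matrix (GLCM) texture-feature maps (entropy, sum entropy, difference
    entropy, energy, contrast, homogeneity) from quantized brain volumes,
    classifies subject groups with a small tanh multilayer perceptron trained
    by Levenberg-Marquardt inside a repeated nested cross-validation with
    univariate t-test feature selection, explains trained models with
    layer-wise relevance propagation (epsilon rule), and clusters subjects'
    positive-relevance heatmaps with affinity propagation.  A synthetic
    phantom-cohort generator plants texture-only group differences so the
    whole pipeline is testable without clinical data.  Includes a minimal
    NIfTI-1 reader/writer so that registered volumes can be exchanged with
    standard neuroimaging tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
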