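Package: voxmed
Title: Voxel-Wise Serial Mediation Analysis of Brain Structure, Function,
    and Task-Switching Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate serial mediation modelling for volumetric
    neuroimaging data. Fits, at every voxel of a gray-matter analysis mask,
    the path model age group -> gray-matter volume -> task activation ->
    global switch cost, decomposes the total effect into direct and
    product-of-coefficients indirect effects (a*f, d*e, a*b*e), and tests the
    indirect-effect maps with threshold-free cluster enhancement (TFCE) and
    max-statistic permutation inference with family-wise error correction,
    followed by an effect-size (%IND) filter and cluster-table reporting.
    Includes a synthetic-data generator that plants known path coefficients
    in spatially smooth volumes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
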