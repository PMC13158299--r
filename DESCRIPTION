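Package: retromorph
Title: Virtual Reconstruction and Allometry Analysis for 3D Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the virtual reconstruction of deformed specimens and
    for shape/allometry statistics on 3D landmark configurations.  Implements
    generalized Procrustes superimposition with tangent-space projection,
    thin-plate-spline warping with bending-energy semilandmark sliding and
    missing-landmark estimation, bilateral retrodeformation via the closed-form
    halfway (matrix square root) transform, reference-hyperplane restoration in
    a principal-component framework, residual-randomization permutation MANCOVA
    (Type I/II/III sums of squares, optional phylogenetic generalized least
    squares), a rarefaction plus label-permutation slope-homogeneity protocol
    for unbalanced two-group designs, and a measurement-error protocol based on
    Procrustes ANOVA repeatability.  A synthetic-data module generates landmark
    samples with known allometric structure so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    permute,
    pracma,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
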