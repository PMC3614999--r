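Package: leucidelim
Title: Integrative Species Delimitation for Sympatric Leuciscine Fishes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for integrative species delimitation of
    sympatric leuciscine fishes combining geometric morphometrics and
    molecular data.  Implements generalized Procrustes superimposition,
    thin-plate-spline partial warps, canonical variate analysis with
    leave-one-out cross-validation and permutation tests, a
    classification-tree identification key on meristic counts, alignment
    summary statistics (variable sites, haplotypes, diagnostic
    substitutions and indels), pairwise genetic distances with principal
    coordinate analysis, and a two-block partial least squares model of
    shape-genetics covariation.  A synthetic four-species data generator
    with planted, parameter-controlled structure provides ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
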