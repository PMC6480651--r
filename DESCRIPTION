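Package: subnucleaR
Title: Sub-Nuclear Protein Localization from Evolutionary Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the sub-nuclear compartments (chromatin, nucleolus,
    nuclear speckle, and ten further membrane-less structures) in which a
    nuclear protein functions, and whether a protein "travels" between the
    nucleus and other cellular compartments. Predictions combine
    homology-based annotation transfer from alignment hits with de novo
    classification by one-vs-rest support vector machines over the profile
    string kernel, which counts k-mers conserved in a protein's evolutionary
    profile. The package also provides the surrounding analytics: reliability
    indices, stratified cross-validation, confusion-matrix accuracy measures
    and ROC/AUC, compartment composition spectra with confusion-matrix bias
    correction, agreement scores between multi-label predictions, Gene
    Ontology term enrichment, protein-protein interaction odds ratios per
    compartment pair, and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    kernlab,
    Matrix,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
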