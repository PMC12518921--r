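Package: spaedr
Title: Segmentation of Protein Domains from AlphaFold Predicted Aligned Error Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments modular proteins (phage endolysins and similar
    multi-domain proteins) into domains, linkers and terminal disordered
    regions by single-linkage hierarchical clustering of the predicted
    aligned error (PAE) matrix produced by AlphaFold-family structure
    predictors. Provides readers for the common PAE JSON dialects,
    evaluation metrics for predicted versus reference delineations
    (intersection-over-union and domain-boundary-distance scores with
    boundary accuracy/sensitivity permissibility curves), a synthetic PAE
    generator with exact ground truth for validation, and batch
    segmentation/evaluation front ends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'batch.R'
    'chopping.R'
    'methods.R'
    'metrics.R'
    'pae_io.R'
    'segment.R'
    'synth.R'
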