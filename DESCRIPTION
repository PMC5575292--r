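Package: plofpred
Title: Annotation and Pathogenicity Prediction for Putative Loss-of-Function Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates putative loss-of-function (pLoF) variants -- premature
    stop SNVs, frameshift indels, and canonical splice-site variants -- against
    gene models and a reference genome, computes a 108-slot feature bundle
    (functional domains, nonsense-mediated decay, evolutionary conservation,
    protein-protein interaction network proximity, allele frequencies, and
    gene-level covariates), emits annotation-artifact flags, and classifies
    each variant as benign, recessive disease-causing, or dominant
    disease-causing with a stratified random-forest ensemble that reports
    three class probabilities and a High/Low confidence label. Ships a
    synthetic fixture generator (genome, gene models, annotation tracks,
    labeled training corpus) so the whole pipeline runs without external
    resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
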