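Package: pairedexome
Title: Paired Primary-Tumor and Brain-Metastasis Exome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based comparative genomics for paired primary lung tumor
    and brain metastasis exomes without a matched normal: quality and
    germline-catalog filtering of per-sample variant tables, three-way
    paired classification of variants into shared (truncal),
    primary-specific and metastasis-specific sets, metastasis-vs-primary
    coverage log-ratio copy-number segmentation by circular binary
    segmentation with mode-based zero-level calling, 96-trinucleotide
    mutational spectra with PCA and hierarchical clustering (cosine
    distance, Ward linkage), and per-patient trunk/branch phylogenies with
    cross-patient recurrence and protein-domain overlap reports. Includes
    a seeded synthetic paired-cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
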