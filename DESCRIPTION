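Package: stpls
Title: Soft-Thresholding Partial Least Squares for Genotype-Phenotype Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds evolutionary-distance genotype features from
    pairwise-alignment best-hit scores against a reference gene set, fits
    sparse soft-thresholding partial least squares (ST-PLS) regression
    models per phenotype with cross-validated selection of the number of
    components and the shrinkage level, and post-processes the selected
    gene sets with permutation null distributions, pleiotropy summaries,
    and gene-category enrichment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
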