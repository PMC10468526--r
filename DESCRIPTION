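Package: hepscreen
Title: Screening for Age-Associated Genes in Hepatocyte Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for screening age-associated genes in
    liver single-cell RNA-seq: cell quality-control filtering, per-cell RPKM
    normalization, albumin gating of hepatocytes, positive-cell calling at an
    RPKM threshold, per-group positive-cell rates with old-minus-young
    difference ranking, ortholog-filtered candidate selection, and
    within-group gene-gene and gene-set correlation analysis. Includes a
    negative-binomial count simulator that plants a senescent hepatocyte
    subpopulation with co-expressed marker genes, so the whole screen can be
    exercised and validated against known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
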