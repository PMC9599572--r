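Package: commniche
Title: Constraint-Based Niche Analysis and Multi-Omics Summaries for Microbial Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis of small stoichiometric models, phenotype-guided
    gapfilling against a universal reaction set, mixed-bag community model merging,
    and fundamental versus realized niche computation for defined microbial
    consortia degrading polymeric carbon sources such as chitin. Also provides the
    accompanying multi-omics summary statistics: per-species median-of-ratios count
    normalization, negative-binomial differential expression with
    Benjamini-Hochberg adjustment, per-species transcript relative-abundance
    profiles, metabolite differential abundance, annotation-based pathway coverage
    scoring, and ground-truth-known synthetic data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
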