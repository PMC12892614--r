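Package: sncflow
Title: Noncanonical Small RNA Profiling, Signatures and Risk Scoring in Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of noncanonical small noncoding RNAs
    (tRNA-, rRNA- and Y RNA-derived fragments) in blood small-RNA
    sequencing data. Annotates collapsed reads to parental RNAs by exact
    matching, aggregates species to family-level reads-per-million
    expression, profiles cleavage positions and length distributions,
    prioritises differentially expressed families with a covariate-adjusted
    linear model and Bonferroni correction, derives commonly dysregulated
    signatures, computes a z-sum risk score with cross-validated ROC/AUC
    evaluation and DeLong comparisons, performs small RNA-gene
    co-expression with rank-based pathway scoring and hypergeometric
    enrichment, and quantifies cross-cohort baseline divergence. Includes a
    synthetic cohort generator with planted ground truth so every stage is
    testable without access to patient sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
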