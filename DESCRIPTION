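Package: covaudit
Title: Depth-of-Coverage Completeness Audit for Exome and Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Audits how completely short-read sequencing platforms cover the
    coding genome at base resolution. Implements exon eligibility filtering
    (unique mappability, assembly identity, common-CNV exclusion),
    complete-coverage statistics at a configurable per-base depth cutoff with
    across-sample confidence intervals, variant-level coverage assessment,
    GC-stratified depth profiles, near-miss reporting for clinical gene
    panels, and a coefficient-of-variation decomposition of coverage
    uniformity into reproducible (intra-individual) and noise-like
    (inter-individual) components. A bundled synthetic depth simulator with
    capture-style GC bias and lognormal exon-level capture efficiency makes
    the whole pipeline testable end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
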