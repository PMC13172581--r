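Package: ladscape
Title: Lamina-Associated Domain Remodeling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing remodeling of lamina-associated domains
    (LADs) between conditions from broad enrichment tracks (e.g. lamin B1
    CUT&Tag). Builds condition-level consensus domain sets from replicate
    calls, partitions genome change into five categories (common LAD,
    lost/gained whole domains, lost/gained edges), computes coverage and
    domain-size statistics, signal metaprofiles over domain bodies and
    boundaries, gene-feature and TSS-distance redistribution, a Fisher's
    exact enrichment test linking LAD gain to gene downregulation, and a
    coverage-based ordination of domain sets. Includes a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
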