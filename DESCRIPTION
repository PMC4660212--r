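Package: ctascreen
Title: Multidimensional siRNA Screen Analysis for Cancer-Testis Antigens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed siRNA screens of cancer-testis
    antigens (CTAs) across a panel of tumour-derived cell lines: presence
    calling from NanoString-style counts with qPCR rescue of ambiguous
    probes, greedy and exact maximum-coverage selection of a cell-line
    testbed, viability-corrected control normalization and per-stratum
    z-scores for cell-biological and ligand-induced reporter assays,
    rule-based hit calling with Student's t-test significance filtering,
    siRNA pool deconvolution, per-gene Kolmogorov-Smirnov effect
    comparisons, and hypergeometric gene-set overlap tests. Includes a
    seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
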