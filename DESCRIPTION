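Package: xbp1flux
Title: Junction-Based XBP1 Splicing Quantification and Downstream Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking IRE1-alpha/XBP1s pathway inhibition to
    transcriptome changes in prostate cancer cells. Quantifies the spliced XBP1
    isoform from STAR splice-junction tables (reads supporting the XBP1s junction
    per million total spliced reads) and tests differential usage with a negative
    binomial GLM; performs simplified negative-binomial Wald differential
    expression with median-of-ratios depth normalization; measures concordance
    between two perturbations (fold-change quadrants, exact binomial overlap of
    top-N gene lists); scores gene-set enrichment of fold-change shifts by
    Kolmogorov-Smirnov and Fisher's exact tests; computes signature-activity
    scores with quantile normalization and Kaplan-Meier/log-rank survival
    stratification; and evaluates drug-combination synergy against a fractional
    response criterion. A seeded synthetic-data generator emulates every input so
    the full pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    DESeq2,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
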