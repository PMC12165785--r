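Package: crisprselect
Title: Functional Scoring and ACMG/AMP Classification for CRISPR-Select
    Knockin Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for competitive CRISPR knockin fitness assays
    of the CRISPR-Select type. Parses amplicon allele-count tables, classifies
    reads into variant, synonymous internal-control (WT'), frameshift-indel
    and other classes, computes day-2-normalized variant/WT' functional
    scores with replicate aggregation, calibrates assay thresholds from
    classified control variants (ROC, sensitivity/specificity with Wilson
    confidence intervals, OddsPath evidence strength), and classifies
    variants of uncertain significance under the ACMG/AMP framework using
    both the point-based and the qualitative code-combination systems.
    Includes a seeded synthetic-data generator that emulates the count
    structure of the assay so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
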