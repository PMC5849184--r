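Package: coexscreen
Title: Guilt-by-Association Coexpression Screening and Master-Regulator
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline pipeline for guilt-by-association analysis of a query
    gene in a large expression panel: genome-wide Pearson correlation
    screening with Benjamini-Hochberg false discovery rate control and joint
    effect-size classification, directional-bias statistics for curated gene
    sets (Fisher exact, exact binomial sign test, distribution comparisons,
    Gaussian kernel density estimation), gene-set over-representation against
    GMT libraries with deterministic ranking, transcription-factor
    target-set prioritization, and log-odds position-weight-matrix scanning
    of promoter sequences in TSS-relative coordinates. Includes a seeded
    synthetic-data generator that plants a hub gene, a correlated
    transcription factor, a negatively correlated gene module and a promoter
    motif, so every stage of the analysis can be verified against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
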