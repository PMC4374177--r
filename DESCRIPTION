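Package: sleepcline
Title: Latitudinal Variation in Drosophila Sleep from Activity-Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for geographic variation in Drosophila
    melanogaster sleep and locomotor behaviour. Reads Trikinetics-style
    Drosophila Activity Monitor (DAM) beam-cross series, detects sleep bouts
    (five or more consecutive inactive minutes), computes activity, walking
    speed and sleep phenotypes with fly-to-line-to-population aggregation,
    fits latitudinal cline regressions with multiple-testing correction,
    quantifies sunrise anticipation (pre-dawn activity ramping), estimates
    circadian phase and free-running period by chi-square periodogram, and
    tests hypergeometric enrichment of differentially expressed genes in
    high-FST genomic windows. A synthetic-data module generates DAM-like
    behavioural recordings with a programmed sleep cline and gene/window
    fixtures with programmed enrichment so the full pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
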