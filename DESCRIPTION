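Package: coloczone
Title: Genome-Wide Feature Co-Localization and Zonal Architecture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Window-based analysis of genomic feature co-localization.
    Bins chromosomes into fixed-size windows, removes assembly-gap
    windows, quantifies interval tracks per window as element counts,
    coverage density, or score-weighted intensity, and computes all
    pairwise Pearson and Spearman co-localization coefficients with
    asymptotic p-values. Classifies windows into Genic, Proximal and
    Distal zones by the feature-ratios method, detects top-quantile
    SNP/CNV hotspot windows and their double and triple intersections,
    tests recombination-rate elevation in joint hotspots, and runs
    hypergeometric over-representation analysis of hotspot gene content.
    Includes a synthetic genome-track simulator with planted zones,
    pairwise correlations and hotspots so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
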