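Package: methgrad
Title: Per-Cytosine DNA Modification Density Analysis Along a Transcriptional Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking per-cytosine DNA modification densities
    from targeted bisulfite sequencing to a within-cell-type transcriptional
    gradient across the nine segments of the mouse small intestine. Computes
    read-count-based modification densities with coverage and saturation
    filters, per-cytosine Pearson correlations with relative mRNA levels
    expressed as signed log p-values (SLP), calls clusters of three or more
    significantly associated cytosines within 500 bp, performs age and diet
    group contrasts with Welch tests and LOESS-smoothed positional delta
    profiles, quantifies expression by the delta-delta-Ct method with
    repeated-measures ANOVA, and normalizes ChIP-qPCR to percent input with
    IgG background subtraction. A synthetic-data module generates methylation
    count tables, qPCR Ct tables and ChIP Ct tables with planted effect sizes
    so that every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
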