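Package: screenvote
Title: Replicate-Vote Hit Calling for Positive-Selection Pooled CRISPR
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of genome-wide positive-selection CRISPR knockout
    survival screens from sgRNA read counts. Implements per-sgRNA fold
    enrichment against the baseline sgRNA distribution with absolute and
    relative read thresholds, a candidate-gene vote requiring support
    from multiple sgRNAs across independent screens, top-hit-normalized
    log2 gene scoring, exact-match spacer counting from FASTQ reads, a
    negative-binomial screen simulator with planted resistance genes and
    off-target/passenger artifacts, and recovery metrics against
    simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
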