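Package: mamut
Title: Mutation-Accumulation Experiment Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mutation-accumulation (MA) experiments followed by
    whole-genome sequencing: ingestion and filtering of per-line variant call
    sets, pooled mutation-rate estimation with exact Poisson confidence
    intervals, base-substitution spectrum and equilibrium GC-content analysis,
    synonymous/nonsynonymous expectation under a ts/tv-weighted null,
    insertion-deletion balance and simple-sequence-repeat (SSR) hotspot
    analysis. Includes a synthetic MA-experiment generator with known
    ground-truth mutation parameters so every stage of the pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
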