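Package: nitrocircuit
Title: Cis-Element Calling, Signed-Circuit Assembly and Knockout Prediction
    for Nitrate-Responsive Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting small nitrate-responsive transcription
    factor circuits such as the ARF18/ARF9-DREB26-ANAC032-NLP6/7-NIR1
    sub-circuit of Arabidopsis and its tomato counterpart. Provides
    TSS-anchored promoter-region extraction with open-chromatin peak
    handling, FIMO-style motif scanning (position weight matrices and
    degenerate IUPAC consensi) with exact dynamic-programming p-values,
    Benjamini-Hochberg adjustment and a paired auxin-response-element rule,
    signed regulatory network assembly from layered evidence, network-motif
    census (autoregulation, feedforward loops, coherence), qualitative
    knockout-effect prediction under a downstream-epistasis rule,
    ortholog-aware cross-species network comparison, printed quantification
    formulas (2^-ddCt, ratiometric dual-luciferase normalization, GO odds
    ratio), and seeded synthetic-data generators so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
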