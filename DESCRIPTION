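Package: apasignal
Title: Genome-Wide Polyadenylation Signal Discovery and Stage-Specific APA Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising alternative polyadenylation (APA)
    from 3'-end sequencing cleavage-site tables: clustering of cleavage events
    into poly(A) site clusters, internal-priming (A-rich stretch) filtering,
    genomic-region annotation, usage-based site classification
    (strong/weak/universal/unique plus matched controls), discovery of
    over-represented poly(A) signal hexamers against a first-order Markov
    background with self-overlap-corrected variance, region-specific cis-element
    schemas with position frequency matrices, and entropy-based identification
    of developmental stage-specific sites (ROKU-style, with a one-step Tukey
    biweight adjustment). Includes a synthetic-data generator that plants
    signals, artifacts and stage profiles with a known truth table so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
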