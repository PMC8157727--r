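Package: diffprobe
Title: Differential Reactivity Detection for High-Throughput RNA Structure Probing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially reactive nucleotides between two conditions
    in high-throughput RNA chemical structure probing experiments (SHAPE, DMS,
    SHAPE-MaP). Works directly from per-nucleotide read coverage and event
    counts (reverse-transcription drop-offs or mutations): log event-rate
    ratios for all treatment-control comparisons are variance-stabilized
    against coverage, converted to empirical P-values using a control-control
    null distribution, and decoded with a four-state beta-uniform mixture
    hidden Markov model whose posterior quantifies differential modification
    at single-nucleotide resolution. Includes a synthetic-data generator with
    known ground truth for end-to-end validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
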