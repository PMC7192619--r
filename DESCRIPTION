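Package: axonedit
Title: Differential and Site-Specific A-to-I RNA Editing Analysis from Base Counts
Version: 0.1.0
Authors@R:
    person("axonedit", "developers", email = "axonedit@example.org", role = c("aut", "cre"))
Description: Quantifies adenosine-to-inosine (A-to-I) RNA editing from per-site
    base-call counts and implements two complementary statistical analyses:
    transcriptome-wide differential editing between two cellular compartments
    (e.g. a neuron's axon versus its cell bodies) using paired replicate
    designs, two one-tailed Welch t-tests per site and per-tail
    Benjamini-Hochberg false discovery rate control; and detection of
    site-specific in vitro editing events on an amplicon against an exact
    binomial sequencing-error null. Includes a samtools-pileup reader with
    Phred base-quality filtering, coverage-weighted editing-index and mean
    editing-level summaries, a seeded synthetic-data generator producing count
    tables with the statistical structure the analyses assume, and a
    command-line pipeline wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
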