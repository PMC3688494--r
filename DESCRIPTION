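Package: orgedit
Title: Detection and Differential Analysis of C-to-U RNA Editing in
    Organelle Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying C-to-U RNA editing in plant organelle
    transcripts from strand- and transcript-specific amplicon deep
    sequencing (STS-PCRseq style data). Provides read preprocessing and
    alignment-record filtering, per-library pileups over amplicon
    templates, an empirical position-on-read mismatch-rate model, a
    likelihood-ratio editing-site caller with explicit candidate filters,
    a differential-editing framework (editing-extent change, 2x2
    chi-square tests with Bonferroni familywise control, silenced-plant
    dual-control logic), cross-factor overlap analysis, a cis-element
    similarity scan, and a truth-known read simulator so the whole
    pipeline can be validated end to end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
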