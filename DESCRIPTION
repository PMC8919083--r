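Package: ptsscreen
Title: Proteome-Wide Screening for Peroxisomal Targeting Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens protein sequence sets for candidate peroxisomal matrix
    proteins. Implements C-terminal PTS1 consensus matching, a calibrated
    position-specific scoring model over the C-terminal 12 residues with
    targeted/twilight classification, N-terminal PTS2 nonapeptide detection,
    hydropathy-based transmembrane and secretory-signal exclusion filters,
    a staged screening cascade with per-stage accounting, cross-species PTS1
    motif comparison, and a synthetic proteome generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
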