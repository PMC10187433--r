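Package: prdxswitch
Title: Peroxiredoxin-Gated FOXO1/p53 Dynamics: Simulation and Single-Cell Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the two-phase transcription-factor response to
    hydrogen peroxide stress at single-cell resolution. Implements a deterministic
    model of the 2-Cys peroxiredoxin redox cycle with hyperoxidation, sulfiredoxin
    repair and clearance feedback that gates a FOXO1 nuclear-residence window and a
    delayed p53 phase; a seeded generator of per-cell trajectories, immunofluorescence
    snapshot populations and rendered image fields with ground-truth masks;
    nuclear/cytoplasmic-ring image quantification; control-quantile activation gating
    with quadrant summaries; trajectory feature extraction (phase entry/exit, p53
    onset, exit-aligned averaging, lag and heatmap ordering); and autocorrelation
    analysis of p53 oscillations with dying-versus-surviving comparisons.
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
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    tiff
Config/testthat/edition: 3
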