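Package: secretomap
Title: Self-Organizing Map Integration of Transcriptome and Secretome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters genome-wide RNA-seq expression profiles onto a batch-trained
    self-organizing map (SOM), overlays secreted-protein spectral-count detections
    onto the resulting nodes, selects substrate-responsive and secretion-hotspot
    nodes, and scores node-wise functional-annotation enrichment with the
    hypergeometric test under Benjamini-Hochberg control. Includes median-of-ratios
    count normalization, per-time-point log2 fold changes against a control
    condition, transcription induction factors, node-level transcriptome-secretome
    rank correlation, fixed-layout topography heatmaps, and a negative-binomial
    synthetic-data generator with planted co-regulated blocks for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
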