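Package: msburst
Title: Quantification of Transcriptional Bursting from MS2/MCP Live Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of nascent-transcription live-imaging movies
    of early Drosophila embryos recorded with the MS2/MCP system: nuclei
    segmentation from a histone channel, nearest-centroid tracking, 2D
    Gaussian quantification of transcription spots, threshold-based burst
    calling with per-nucleus bursting statistics, population activity metrics,
    autocorrelation periodicity with a time-shuffled null, and computational
    reconstitution of spatial mRNA patterns under first-order decay. Includes
    a ground-truthed synthetic-movie generator built on the two-state
    telegraph model so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
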