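Package: LiveCellQuant
Title: Lifecycle Quantification from Annotated Live-Cell Phase-Contrast Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cell-population behaviour from per-frame
    bounding-box annotations of live-cell phase-contrast videos. Cells are
    labelled with four morphology classes (living, round, dividing, dead);
    the package reads and writes VIA-, COCO- and CSV-style annotation files,
    scores object detections against ground truth (IoU matching,
    non-maximum suppression, precision/recall/F1, average precision swept
    over IoU thresholds, mAP), derives biological endpoints (class-count
    time series, offset-exponential growth fits with confidence bands,
    growth-defined survival fractions, division and unique-dead-cell
    censuses), and computes conventional radiobiology quantities (plating
    efficiency, clonogenic survival with error propagation, the
    linear-quadratic dose-response model, and Caspase3/7-Sytox gating
    tabulation). An agent-based lifecycle simulator and a detector-noise
    emulator generate ground-truth videos with full lineage for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
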