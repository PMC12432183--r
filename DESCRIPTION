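Package: oriact
Title: Time-Resolved Origin-Activity Analysis for EdU-seq-HU Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of replication-origin activity from EdU-labelled nascent-DNA
    sequencing of hydroxyurea-arrested early S-phase cells. Builds depth-normalized
    binned read tracks and the sigma statistic (normalized reads per bin divided by
    the track standard deviation), calls and ranks early-firing origins, aggregates
    1-kb meta-origin activity profiles, and compares treatments via percent reduction
    in average origin activity and per-origin linear regression. Also provides
    cytometry gating statistics (EdU-positive fraction, DAPI/Cyclin A2 cell-cycle
    classification, paired t-tests) and a synthetic generator that simulates G1
    licensing schedules, origin-anchored read pileups and per-cell intensity tables
    so the whole pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
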