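Package: tmjseg
Title: Segmentation of Temporomandibular Joint Auscultation Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatic segmentation of temporomandibular joint (TMJ)
    auscultation recordings into episodes of combined jaw opening and
    closing. Implements two complementary segmenters: a deterministic
    digital-signal-processing pipeline (rectification, adaptive elliptic
    low-pass filtering at the signal's main harmonic, moving-average
    envelope extraction, peak detection and fractional-amplitude boundary
    placement) and a one-dimensional U-Net with parallel max/min-absolute
    pooling and an LSTM bottleneck, trained with per-sample binary
    cross-entropy. Includes sample-wise evaluation metrics (sensitivity,
    positive and negative predictivity, specificity, Dice coefficient), a
    synthetic stethoscope-signal generator producing labelled corpora with
    patient structure, WAV and annotation-CSV input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
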