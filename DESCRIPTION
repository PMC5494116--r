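Package: excnvss
Title: Copy Number Variant Detection from Exome Read Depth by Scale-Space
    Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from whole-exome sequencing
    read-depth data using Gaussian scale-space filtering of concatenated
    per-base target coverage. Coverage is normalized by a four-step protocol
    (test/control depth ratio with library-size correction, fixed-size
    segmentation, t-score adjustment of segment means, and base-level
    redistribution), decomposed into a multi-scale image by Gaussian
    convolution in the frequency domain, and scanned for inflection-point
    (zero-crossing) contours whose interval means exceed empirical quantile
    baselines. Calls are traced to base resolution and typed as gains or
    losses. A test-only mode requires no matched control. Includes a
    coverage-level exome simulator with CNV spike-ins and a target-level
    FNR/FPR evaluator with threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
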