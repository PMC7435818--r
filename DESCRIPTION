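Package: teafix
Title: Image-Energy Monitoring of Tea Fixation State
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Online process-state monitoring of tea fixation (kill-green) from
    RGB images. Extracts per-channel gray-level histograms ("energy"), locates
    the two troughs of the luma histogram to strip white background and dark
    leaf-overlap shadows, reduces each retained channel to a single attention
    peak mapped to a 2-D feature point, trains per-channel cluster centers by
    averaging over a batch of standard-state images, and classifies monitoring
    batches as normal or abnormal from the total pairwise center distance. A
    synthetic tea-image generator with a controllable fixation-degree parameter
    makes the whole pipeline testable without real images.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    jpeg,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
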