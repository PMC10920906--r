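Package: repeatmeth
Title: Quantification of Repeat DNA Methylation Readouts from Imaging and qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed quantification stack for studies linking cell
    density and adherens-junction signaling to alpha-satellite DNA methylation.
    Provides synthetic generators for fluorescence-complementation reporter
    microscopy stacks, chromatin-mobility movies, MSRE-qPCR and RT-qPCR Ct
    plates and flow-cytometry event tables; per-nucleus spot quantification
    with cell-by-cell background subtraction; single-particle tracking and
    mean-square-displacement analysis with scaled-MAD outlier removal;
    methylation-sensitive restriction enzyme qPCR and delta-delta-Ct relative
    quantification; control-gated median fluorescence intensity; and the
    per-biological-repeat two-condition normalization and testing layer used
    to compare conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tiff,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
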