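Package: spermcasa
Title: Computer-Assisted Sperm Analysis: Accumulation Maps, Functionality
    Classification and Concentration Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computer-assisted sperm analysis (CASA) from microscopy
    stills and frame-sequence videos. Builds per-pixel sperm-accumulation heat
    maps with boundary correction and Jet-colormap rendering for chemotaxis
    accumulation assays, tracks counts in concentric regions of interest over
    time, classifies fluorescence-stained spermatozoa into five plasma-membrane
    and acrosome subpopulations from their pixel hue composition, and estimates
    sperm concentration (millions of cells per mL) from counts in a chamber of
    known depth. Includes a seed-deterministic synthetic image and video
    generator with planted ground truth for end-to-end validation, and a small
    agreement-statistics utility (correlation and Bland-Altman bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
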