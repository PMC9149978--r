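Package: pseudoMR
Title: Synthetic Weighted MR Images from CT via Quantitative Tissue Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic spin-echo weighted MR images from a real CT
    slice. Per-pixel T1, T2 and proton-density maps are estimated from
    variable-TR and variable-TE spin-echo series, mapping surfaces from
    windowed CT-number statistics (mean, standard deviation) to the three
    intrinsic parameters are learned by piecewise-linear or nearest-neighbour
    scattered-data interpolation, and weighted images at arbitrary TE/TR are
    synthesized from the forward spin-echo signal model. Includes fuzzy
    C-means segmentation for region extraction, regression-slope and
    percentage root-mean-square-difference similarity metrics, a digital
    multi-tissue CT/MR phantom simulator with known ground truth, and a
    configurable end-to-end pipeline with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    minpack.lm,
    interp,
    FNN,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
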