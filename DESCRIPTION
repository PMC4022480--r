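Package: cyberloop
Title: In-Silico Closed-Loop Control of Gene Expression in Growing Yeast Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulation platform for external feedback control of
    gene expression in Saccharomyces cerevisiae. Implements a discrete-time
    proportional-integral controller whose output is encoded as a binary
    galactose/glucose input via pulse-width modulation, a Smith-type predictor
    compensating transcriptional delay, a hybrid (input-switched) delay
    differential equation model of the five-gene IRMA synthetic network and a
    one-gene GAL1 promoter model, a virtual growing cell population with
    extrinsic parameter variability, and a microscopy-style measurement chain
    (synthetic frame rendering, Otsu binarization, convex-hull region grouping,
    circular Hough transform cell localization, masked fluorescence
    quantification). Includes Cohen-Coon tuning from step responses, canned
    in-silico experiment recipes, and tracking/regulation performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
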