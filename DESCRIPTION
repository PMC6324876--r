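Package: ffnquant
Title: Quantification of Evoked Fluorescent False Neurotransmitter Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for evoked transients of pH-sensitive
    fluorescent false neurotransmitters (FFNs) imaged in brain slices.
    Extracts baseline-corrected percent dF/F traces from two-photon movies,
    scores transients by trapezoidal area under the curve, quantifies
    punctate anatomy in baseline images with Canny edge filtering, fits
    decay kinetics on log-transformed traces, analyses the spatial
    dispersion of release hotspots with a pair-distance permutation test,
    and provides the paired/unpaired t-test and repeated-measures and mixed
    ANOVA comparisons used for such experiments. A synthetic-data generator
    emulates the imaging experiments (stimulus trains, region-specific
    kinetics, calcium dependence, frequency facilitation, photobleaching,
    punctate anatomy, pixel noise) with known ground truth so that every
    stage of the pipeline is verifiable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
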