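Package: voltfret
Title: Quantification of Voltage-Dependent ERK Activity from FRET and FLIM Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell ERK kinase activity from
    ratiometric CFP/YFP FRET biosensor time-lapse recordings acquired under
    high-potassium perfusion or voltage-clamp protocols: background
    subtraction, dish-reference ratio normalization, the per-cell percent
    ERK activity statistic with its non-responder exclusion rule, phase-wise
    trace extrema, donor-lifetime (FLIM) estimation by binned
    truncated-exponential maximum likelihood, mitotic-activity binning and
    normalization, Nernst-equation membrane-potential prediction, and the
    correlation and group-comparison summaries used to relate ERK activity
    to membrane potential. A seeded synthetic-data generator emulates the
    imaging experiments (dish gain variation, cell-to-cell response
    variability and non-responders, asymmetric activation kinetics,
    saturating EGF responses, photon-decay histograms, Poisson mitosis
    events, rendered two-channel image stacks) so the whole pipeline is
    testable end to end without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
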