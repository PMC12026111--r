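Package: adaptivepcr
Title: Adaptive PCR Cycling Control, Photothermal Instrument Simulation and qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fluorescence-controlled ("adaptive") PCR, in which
    thermocycling is driven by optical monitoring of L-DNA hybridization
    sensors instead of preset temperatures and times. Implements the
    cycling-control algorithm (smoothed fluorescence derivatives, streaming
    Gaussian fits, switch-point prediction and stability statistics), a
    closed-loop simulator of a laser-heated photothermal thermocycler
    (lumped thermal dynamics, two-state sensor melt models, hydrolysis-probe
    chemistry, 30 Hz detector sampling), quantitative PCR analysis
    (baseline normalization, fractional Cq by monotone spline, window-of-
    linearity single-sample efficiency, standard curves, limit of
    detection, cycle-time summaries), salt-adjusted oligonucleotide melting
    temperatures, and Beer-Lambert transmission arithmetic for laser
    heating and nanorod fluorescence blocking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
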