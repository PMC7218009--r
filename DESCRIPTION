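Package: motorunit
Title: Closed-Loop Motor Unit Simulation with Dendritic Persistent
    Inward Currents and Muscle Spindle Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a closed-loop mammalian motor unit: a
    multi-compartment branched-cable motoneuron with relocatable
    dendritic L-type (Cav1.3) calcium hot-spots that carry the
    persistent inward current (PIC), a three-module muscle model
    (spikes to sarcoplasmic calcium, calcium to activation, activation
    to isometric force), and length-dependent muscle-spindle afferent
    drive distributed over the proximal dendrites. Provides somatic and
    dendritic triangular stimulation protocols, warm-up protocols,
    calibration routines that pin free conductances to effective
    somatic currents measured under voltage clamp, and input-output
    indices (DCT, DCI, DFG, firing-type classification, warm-up
    detection) for quantifying PIC-mediated hysteresis in firing and
    force.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
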