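Package: spinalloop
Title: Analysis of Autogenic Spinal Interneuron Feedback Loops from
    Spike and EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and characterizing "autogenic"
    excitatory spinal interneurons (agINs) from simultaneously recorded
    spike trains, multichannel electromyograms (EMG), task-trial event
    tables, and peripheral nerve stimulation events.  Implements
    spike-triggered averaging of rectified EMG with incremented-shifted
    average detrending and multiple-fragment significance testing,
    postspike-effect measurement and classification, peristimulus time
    histogram analysis with volley-referenced central latency, trial-level
    afferent-gain labeling, EMG burst detection with normalized-rank
    bias tests, sparse Bayesian (automatic relevance determination) lagged
    decoding of interneuron spiking from EMG, reconstruction of task EMG
    by convolving movement-aligned firing histograms with postspike-effect
    snippets, and a closed-loop nonlinear segmental reflex simulator with
    Ib/Ia feedback-gain fitting and sensitivity sweeps.  A seeded
    synthetic-session generator with recorded ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
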