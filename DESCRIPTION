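Package: starcea
Title: Cohort Markov Cost-Effectiveness Model of the STAR Care Pathway for
    Chronic Pain After Knee Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-utility modelling of the STAR
    (Support and Treatment After Replacement) care pathway for chronic pain
    after total knee replacement, compared with usual postoperative care.
    Implements a two-state (chronic pain / no chronic pain), time-dependent
    annual-cycle cohort Markov model over a five-year horizon with NHS-
    perspective costs and QALYs, the parameter-derivation procedures behind
    its inputs (Oxford Knee Score pain-subscale state classification,
    transition-probability estimation from longitudinal panels,
    area-under-the-curve QALYs with baseline-utility adjustment,
    percentage-of-potential-change utility projection, and percent-change
    cost projection), declarative scenario analyses, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves and a
    confidence ellipse on the cost-effectiveness plane, and a synthetic
    patient-panel generator emulating the trial-like and cohort-like data
    the derivation stages consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
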