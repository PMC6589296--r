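Package: pesuflow
Title: Discrete-Event Simulation of Emergency Department and Psychiatric
    Emergency Unit Patient Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Capacity-planning toolkit for emergency departments (EDs) that
    operate a dedicated psychiatric emergency services unit (PESU). Provides
    a generator of NACRS-like synthetic visit histories, ICD-10 mental-health
    grouping, input modelling (exponential interarrival and lognormal
    length-of-stay fits, acuity and disposition mixes), an annual demand
    forecasting battery with mean-absolute-deviation model selection, a
    discrete-event simulation of ED/PESU patient flow with finite bed
    capacity and a PESU transfer list, baseline calibration against
    historical validation targets, and scenario experiments for demand
    growth, substance-abuse diversion programs, cannabis legalization, and
    PESU bed expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
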