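Package: sigwhistle
Title: Signature Whistle Identification and Characterisation from Annotated Dolphin Whistle Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and characterising bottlenose dolphin
    signature whistle types from annotated time-frequency whistle contours.
    Assembles contours into whistles (single-element, connected and
    disconnected multi-loop), builds a catalogue of repeatedly emitted
    whistle types (REWTs), applies the SIGID temporal bout criteria to
    flag signature whistle types, measures standard acoustic parameters
    (start/end/min/max/peak frequency, duration, inflections, slope
    aspects), computes inter-whistle and inter-loop interval statistics
    with boat-noise exclusion, scores multi-judge visual classification
    tasks with Fleiss' kappa, and models per-encounter signature-type
    diversity against group composition with penalized-spline generalised
    additive models. A synthetic-data generator produces complete
    annotated datasets with planted signature types so the whole pipeline
    is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
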