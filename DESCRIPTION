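Package: fociseg
Title: Simulation and Analysis of Bacterial Chromosome Segregation from
    Fluorescent Foci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A stochastic single-cell simulator of the choreography of
    chromosome segregation in rod-shaped bacteria with a longitudinally
    organized chromosome (modeled on Pseudomonas aeruginosa), together
    with the foci-localization analysis pipeline used in snapshot
    microscopy studies: focus counting, new-pole orientation against a
    terminus-proximal reference locus, size-binned segregation curves,
    median/quartile position summaries, interfocal colocalization
    statistics, replisome focus summaries, and Ori/Arm/Ter region
    classification. Populations are sampled from the steady-state
    exponential age distribution; an observation model adds localization
    noise, missed detections and sub-resolution merging so that simulated
    foci tables look like segmentation-tool exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
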