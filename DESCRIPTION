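Package: myotrace
Title: Simulation and Analysis of Isometric Muscle-Strip Force and
    Calcium-Transient Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of synchronized isometric force and
    fura-2 ratiometric calcium-transient recordings from isolated cardiac
    (atrial) muscle strips paced at a fixed rate: beat segmentation,
    per-twitch kinetic feature extraction (amplitudes, time-to-peak,
    half-relaxation/half-decay times, normalized maximal rates),
    force-length, slow-force-response and post-rest-potentiation protocol
    analyses, and nonparametric group comparisons. Includes a calibrated
    forward model of healthy (CONT) and monocrotaline-treated (MCT) rat
    right-atrial strip behavior so that every stage of the pipeline can be
    exercised and validated on synthetic recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
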