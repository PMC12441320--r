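Package: hebtracks
Title: Morphometrics, Classification and Kinematics of Tridactyl Dinosaur Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative study of tridactyl (three-toed)
    dinosaur footprints: landmark-based track measurement (length, width,
    digit lengths, toe extension, interdigital angles), derived ratios
    (length-to-width, mesaxony, digit proportions), a deterministic
    rule engine that assigns tracks to the Hebridean morphotype series,
    trackway geometry (pace, stride, pace angulation, width of angulation)
    with trackmaker hip-height, velocity and gait estimation, and
    assemblage-level summaries (subgroup means, abundances, bearing roses,
    metric correlations). A synthetic track generator with an explicit
    wear model makes every pipeline stage testable without external data.
    Ships an 85-track reference measurement table transcribed from the
    primary literature on the Valtos and Lub Score tracksites (Isle of
    Skye, Scotland).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
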