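Package: slopecell
Title: Place-Cell Rate Maps, Remapping and Theta Phase Precession on a
    Tiltable Linear Track
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for dorsal-CA1 place-cell recordings from a
    tiltable linear shuttle track (0, 15 and 25 degrees of tilt, uphill and
    downhill running). Segments shuttle runs into trials, builds occupancy
    and firing-rate maps on a 2.5 cm grid, detects place fields, computes
    spatial information, sparsity and coherence, classifies six-way
    remapping between tilt conditions, evaluates spatial correlations
    against shuffle null distributions, and fits theta phase precession by
    circular-linear regression. A ground-truthed synthetic session
    generator (shuttle trajectories, theta-modulated Poisson place cells,
    synthetic theta LFP) makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
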