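Package: probene
Title: Proliferation and Benevolence Decomposition of Microbial Health Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for dissecting how microbes affect host health in
    experimental infections. Health outcomes are regressed on microbial
    density within host types and microbial strains, so that host defence
    can be partitioned into resistance (mean microbial density) and
    tolerance (slope of health on density), and microbial effects into the
    analogous traits of proliferation and benevolence. Includes ANCOVA and
    binomial-GLM tests for variation in each trait, classification of
    effector molecules from wild-type versus isogenic-knockout contrasts
    as benevolence, malevolence or proliferation factors, a synthetic
    infection-experiment simulator with known ground truth, Monte-Carlo
    power analysis, density-overlap and linearity diagnostics, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
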