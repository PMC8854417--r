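Package: flyvis
Title: Comparative Morphometrics and Adaptive Evolution of Fly Visual and
    Antennal Sensory Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of insect peripheral sensory
    morphology on phylogenies, built around miltogrammine flesh flies with
    contrasting host-finding strategies (satellite vs non-satellite).
    Derives eye and antennal traits from linear SEM measurements (spherical
    shell eye area, hexagonal ommatidial facet area, ommatidium counts,
    interommatidial angles, body-mass allometry), maps a binary behavioural
    regime onto an ultrametric tree by enumerating all Fitch
    maximum-parsimony reconstructions, fits Hansen-type Ornstein-Uhlenbeck
    adaptive regressions (phylogenetic half-life, stationary variance,
    optimal and evolutionary slopes, phylogenetic R squared) with AICc model
    selection, and computes the non-phylogenetic group contrasts and
    size-relative correlations. A seeded synthetic-data generator (pure-birth
    trees, regime paintings, exact Brownian-motion and Ornstein-Uhlenbeck
    trait simulation with specimen-level noise) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
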