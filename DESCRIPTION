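Package: phenomaze
Title: Behavioural Phenotyping of Mouse Maze Trajectories and Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative behavioural phenotyping of inbred mouse
    strains from tracked trajectories and histological sections. Computes
    Morris water task measures (escape latency, swim length and speed, the
    corridor-based swim error index, path efficiency ratio, probe-trial
    quadrant occupancy), open-field locomotion measures (path length, binned
    speed, central-zone activity, stop counts), and balance-beam stride
    metrics; classifies swim search strategies into eight classes with a
    deterministic rule cascade and derives spatial-strategy improvement
    rates; performs section-based morphometry (Cavalieri volumetry, cortical
    thickness aggregation, threshold/watershed particle counting for cell
    density); and provides the rank-based group-comparison layer
    (Mann-Whitney U, Kruskal-Wallis H, Spearman rho, Bonferroni families).
    A seeded synthetic-data generator produces strategy-conditioned swim
    paths, open-field exploration, stride series and Nissl-like section
    images with known ground truth, so the whole pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    withr,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
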