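Package: wgdfate
Title: Homeologue Expression Fates and Duplicate Retention After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the aftermath of whole-genome duplication
    (WGD) in salmonid fish. Classifies the regulatory fates of homeologue
    pairs (conservation, neofunctionalization, subfunctionalization and
    on-off partitioning) from tissue expression profiles calibrated against
    a diploid outgroup, clusters expression profiles with Ward linkage on
    correlation distance and tests cluster-pair enrichment of homeologue
    divergence by randomization, labels duplication nodes in gene trees and
    assigns them to duplication eras (Ts3R, Ss4R, small-scale duplications)
    to tabulate conditional duplicate retention with the associated
    two-proportion and odds-ratio statistics, and computes windowed
    homeologue sequence-similarity tracks and transposable-element
    divergence landscapes. A seeded synthetic-data generator with recorded
    ground truth makes every stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
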