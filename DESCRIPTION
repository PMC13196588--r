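Package: phageresist
Title: Quantitative Analysis of Phage-Resistance Phenotypes and Resistance Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bacterial resistance to virulent phages from
    plate-reader and count data: the relative bacterial growth (RBG) statistic
    with kernel-density threshold calibration and bootstrap confidence
    intervals, cross-resistance matrices with hierarchical clustering, growth
    kinetics (maximum growth rate, area under the curve), fitness-cost metrics
    (relative growth rate, competition fitness, efficiency of plating,
    adsorption rate), loss-of-function variant filtering with receptor-pathway
    assignment and population allele-frequency trajectories, transposon
    insertion-sequencing enrichment, and a seeded synthetic-data generator so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
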