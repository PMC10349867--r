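Package: porecology
Title: Quantitative Analysis of Biofilm Community Succession in Porous
    Microfluidic Habitats
Version: 0.1.0
Authors@R:
    person("Porecology", "Developers", email = "porecology@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking the spatial segregation of biofilm-forming
    and free-living bacteria in porous microfluidic habitats: per-grain
    biofilm thickness and roughness from confocal-style images, colloid
    mean travel time from breakthrough curves, absolute qPCR
    quantification and planktonic/biofilm compartment partitioning,
    rule-based classification of pairwise microbial interactions,
    phylogenetic-bin null-model inference of community assembly processes
    (beta-NRI and modified Raup-Crick), and exometabolite trend and
    concordance analysis.  A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
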