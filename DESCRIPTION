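Package: phyloscaling
Title: Sampling Theory for Spatial Patterns of Phylogenetic Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the spatial scaling of phylogenetic diversity (PD)
    under a random community-assembly model. Computes rooted Faith's PD and
    the PhyloSor index of phylogenetic similarity; fits power-law species-PD
    curves with the intercept constrained to the root age, species-area
    relationships and logarithmic distance-decay curves; derives the PD-area
    relationship (exponent z_PD = z * z*) and the phylogenetic distance-decay
    curve from those fits; and tests observed communities against
    random-assembly null models (tip randomizations holding alpha- and
    beta-diversity constant) with confidence envelopes and Mantel tests.
    Includes a BLADJ-style even-spacing node dating routine, megatree
    grafting and root-retaining pruning, and synthetic-landscape generators
    (nested species-area designs, distance-decay designs) so every
    prediction can be verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
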