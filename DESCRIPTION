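Package: chemassembly
Title: Chemodiversity and Community Assembly of Rhizodeposits and Active Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular-formula ecology of rhizodeposits and null-model
    inference of community assembly for rhizosphere studies. Computes
    per-formula molecular characteristics and van Krevelen compound
    classes from FTICR-MS peak tables, chemodiversity and Sorensen
    presence/absence ecology, mass-difference biochemical transformation
    networks, and the three relational metabolite dendrograms (MCD, TD,
    TWCD). Applies phylogeny- and dendrogram-informed betaMNTD/betaNTI
    null models to metabolite and active-community data, classifies
    assembly processes, and couples the two via Mantel tests. Includes
    permutation multivariate statistics (two-way PERMANOVA, Mantel,
    PCoA, exact Wilcoxon enrichment), 13C pulse-label allocation
    accounting, DNA stable-isotope-probing heavy-fraction detection, and
    seeded synthetic-data generators so every stage is testable without
    raw study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
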