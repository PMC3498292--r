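Package: pbflex
Title: Protein Blocks and Flexibility Analysis of Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares the backbone flexibility of two variants of a protein
    from conformational ensembles stored as multi-model PDB files. Implements
    Protein Blocks structural-alphabet assignment and the Neq/deltaNeq
    per-residue flexibility statistics, C-alpha contact counting, Shrake-Rupley
    solvent accessibility with Ala-X-Ala normalisation, center-of-mass
    distances, RMSD/RMSF, essential-dynamics PCA, and representative-frame
    selection. A seeded synthetic-ensemble generator builds backbone ensembles
    from Protein Block recipes so the whole pipeline can be exercised and
    validated without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
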