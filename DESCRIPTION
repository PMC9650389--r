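Package: mepsim
Title: Electrostatic Similarity and Bootstrap Clustering of Peptide-MHC
    Class I Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares peptide-MHC class I complexes by the similarity of
    their molecular electrostatic potentials in a focused cleft region and
    groups them by bootstrap-validated hierarchical clustering, as a proxy
    for T-cell cross-reactivity prediction. Reads and sanitizes PDB
    structures, assigns formal charges and radii, superposes all complexes
    onto a common reference frame, evaluates screened-Coulomb potential
    grids on one shared lattice, restricts comparisons to the molecular
    skin intersected with a cylindrical cleft region, computes Hodgkin
    similarity indices for all pairs, and clusters the complexes with
    complete linkage on correlation distances, attaching multiscale
    bootstrap AU and BP support values to every branch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
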