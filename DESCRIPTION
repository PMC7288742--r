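Package: gypsocom
Title: Community Assembly Analysis of Gypsum Plant Communities Along
    Aridity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Taxonomic, soil-affinity (gypsophily) and phylogenetic
    diversity analysis of perennial plant communities on gypsum soils.
    Computes per-plot richness, inverse Simpson diversity, gypsophily
    range, community mean gypsophily and Rao gypsophily diversity with
    trait-shuffle standardized effect sizes; phylogenetic species
    variability and richness, mean pairwise distance and the net
    relatedness index against an independent-swap null model; and fits
    generalized linear models of each metric on mean maximum temperature
    of the hottest month, mean annual precipitation, their interaction
    and total plant cover, reporting Type-II analysis-of-deviance
    chi-square tables. Includes a synthetic-data generator emulating
    gypsum drylands study designs for calibration and parameter-recovery
    testing.
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
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    car,
    optparse,
    withr
Config/testthat/edition: 3
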