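Package: periband
Title: Peri-Filament Band Histomorphometry and Explant Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the host tissue response around knitted surgical
    mesh implants from stained tissue sections: segments mesh filament
    bundles in brightfield or fluorescence micrographs, draws concentric
    distance bands (50 micrometre increments by default) around the
    filament surface via an exact Euclidean distance transform, and
    measures positive-stain area fractions per band and for the whole
    image. Includes a nonparametric gradient test for diminishing
    peri-filament staining, uniaxial load-elongation analysis of mesh
    explants (pre-load trimming, strain, averaged curves with 95%
    confidence envelopes, segmented toe/linear stiffness fits), derived
    outcome arithmetic (mesh contraction, adhesion area, weight gain)
    with Kruskal-Wallis and Bonferroni-corrected pairwise comparisons,
    and a seeded synthetic-data generator producing micrographs, tensile
    curves and outcome tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    withr,
    jsonlite,
    yaml,
    readr,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
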