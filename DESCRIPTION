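Package: lobulizer
Title: Voronoi Models of Hepatic Lobular Architecture and Zonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the classic (Kiernan) liver lobule as a
    Voronoi tessellation of histology images. Constructs bounded Voronoi
    diagrams from central-vein sites, from centroids of glutamine-synthetase
    (GS) positive areas, or as generalized (object-edge) partitions from
    binary object masks; refines diagrams against septal or portal-tract
    landmarks under a bounded-mismatch constraint; splits compound lobules;
    subdivides every lobule into Rappaport-style zones 1-3 by a concentric
    homothet rule; and scores lobular overlap, zonal landmark accuracy and
    polygon morphometrics. A synthetic-tissue generator produces labelled
    ground-truth images so the whole pipeline can be exercised and validated
    without whole-slide scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    pracma,
    igraph,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
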