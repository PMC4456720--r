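Package: netdoi
Title: Degree-of-Interest Filtering, Annotation-Based Layout and Comparison
    of Integrated Data-Knowledge Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters dense integrated data-knowledge gene networks with
    combinable degree-of-interest (DoI) functions: continuous DoI fields
    derived from numeric node or edge attributes, discrete DoI fields derived
    from annotation knowledge sources (GMT gene sets), importance-weighted
    knowledge DoI, and fuzzy-logic (min/max) combination with per-function
    thresholds. Lays out the filtered subnetworks by annotation-set structure
    using a formal-concept signature partition and a weighted
    Fruchterman-Reingold two-step layout, compares multiple subnetworks in a
    reference-anchored super-graph, and exports static SVG/PNG figures with
    diverging color scales, group isocontours and condition-by-gene heatmaps.
    Includes a deterministic synthetic-fixture generator with planted
    annotation structure and an independent DoI oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    RColorBrewer,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
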