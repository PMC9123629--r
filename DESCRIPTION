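Package: hubscreen
Title: Cross-Disease Interactome Screening for Critical Hub Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens protein-protein interaction networks from several related
    diseases for shared critical proteins. For each disease network it computes
    four node centralities (degree, betweenness, closeness, stress) with a
    Brandes-style single-source accumulation, selects degree-percentile hub and
    hub-like sets, intersects node sets across diseases, and filters the shared
    hub-like candidates through a regulatory action map (activation, inhibition,
    expression layers) by removing candidates isolated in any layer. The
    surviving core is intersected with the cross-disease hubs to yield the
    critical protein set. A seeded scale-free network generator with planted
    shared hubs and a ground-truth manifest supports benchmarking the full
    screening funnel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
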