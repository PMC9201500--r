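Package: rootplast
Title: Root System Architecture Plasticity and Water Productivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pot-based root phenotyping experiments
    under contrasting irrigation regimes. Computes gravimetric water use and
    water productivity from pot-weight time series, aggregates root length,
    surface area, volume and mean diameter from root-segment tables by depth
    layer and diameter class, quantifies phenotypic plasticity with the
    relative distance plasticity index (RDPI), and reproduces the standard
    inferential layer for randomized complete block factorial trials:
    assumption checks, two-way ANOVA, Fisher's LSD compact letter display,
    per-genotype regime contrasts, Pearson correlation panels and
    correlation-matrix PCA. Includes a seeded synthetic-data generator that
    emulates the experimental design, so the whole pipeline is testable
    without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
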