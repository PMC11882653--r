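Package: hydroniche
Title: Fundamental-Niche Quantification for Poikilohydric Lichens from
    Hydration-Resolved CO2 Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to extract water-relations, light-economics and
    carbon-acquisition core parameters (light compensation and saturation
    points, maximum net photosynthesis, dark respiration, the optimal
    thallus water-content range at 90% of maximum net photosynthesis in
    both percent of dry mass and mm rainfall equivalent, specific thallus
    mass, water holding capacity, chlorophyll content) from series of
    light-response curves measured along a drying trajectory in a
    minicuvette system. Includes a calibrated simulator of the measurement
    protocol with known ground truth, species-comparison statistics
    (Shapiro-Wilk screening, one-way ANOVA, Tukey post-hoc tests with a
    compact letter display), a from-scratch proportional-odds ordinal
    regression linking core parameters to an ordinal rank of habitat
    association, and desk-scale realised-niche summaries from occurrence
    records joined to gridded precipitation values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
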