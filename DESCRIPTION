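Package: microfoodweb
Title: Soil Micro-Food-Web Analysis from Nematode and Microbial Community Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the soil micro-food web from genus-level
    nematode and microbial (bacterial, fungal) community tables: nematode
    ecological indices (Shannon diversity, dominance, maturity and
    plant-parasitic indices, channel ratio, Wasilewska index, Chao1),
    metabolic footprints with enrichment/structure indices and the
    functional-footprint faunal profile, carbon-flow ternary mapping of
    the bacterial, fungal and root energy channels, signed co-occurrence
    networks with keystone-taxon ranking, one-way ANOVA with LSD compact
    letters for treatment comparisons, and a seeded negative-binomial
    community simulator for a multi-treatment replicated field design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
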