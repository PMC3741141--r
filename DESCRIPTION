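Package: phenoarc
Title: Time-Resolved Phenotype Connection Mapping and Arc Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps time-resolved phenotype-to-phenotype connections in a
    genetic context. Parses gene-by-phenotype time-course score tables,
    gates gene/phenotype/time events by value thresholds or pooled
    quartiles, derives timed and weighted phenotype connections
    (co-occurrence at a lag, or transitions between most prominent
    phenotypes), reorders phenotype lanes to maximize adjacent connection
    weight, builds per-time-point co-phenotype and synchronous-succession
    gene networks with core/variable classification, clusters succession
    profiles (hierarchical, k-means, 2-component projection), and renders
    deterministic linear, circular and 3D-perspective arc views, heat maps
    and line plots as SVG. Includes a seeded synthetic-screen generator
    and a subcommand-style command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    RColorBrewer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
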