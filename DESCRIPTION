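Package: rhizometab
Title: Correlation-Based Screening of Rhizosphere Soil Metabolomes Along a pH Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for untargeted rhizosphere-soil metabolomics
    along an ordered soil-pH gradient: fumigation-extraction formulas for
    microbial biomass carbon and nitrogen, missing-rate peak filtering,
    detection overlap and content totals, index-metabolite correlation
    screening with signed partitioning and bipartite network export,
    cumulative-content characteristic-compound selection, and trend-pattern
    classification at compound, class and superclass level. Includes a
    seeded synthetic-data generator emulating a three-level pH design with
    planted signed associations, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
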