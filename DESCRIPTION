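Package: serpnet
Title: Surveillance of Search-Engine Poisoning by Illegal Online Pharmacy Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing search-engine-results-page (SERP) audits of
    search-redirection attacks that funnel users to illegal online pharmacies.
    Classifies audited result links, computes prevalence and cumulative
    click-through-rate exposure metrics with a per-rank CTR model (head table
    plus exponential tail), reconstructs the weighted directed redirection
    network from compromised source domains to destination pharmacy domains
    (in-degree, PageRank, hub-concentration summaries, legitimacy and traffic
    joins, GraphML/GEXF export), and ships a seeded generator of synthetic
    multi-country SERP audits with the hub-dominated affiliate-network
    structure observed in the field, so the whole pipeline is testable
    without any live search scraping.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
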