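Package: icsrnet
Title: Drug Co-Reporting Network Analysis for Pharmacovigilance Case Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drug combinations in individual case safety
    reports (ICSRs) from spontaneous-reporting pharmacovigilance databases.
    Implements the inclusion cascade for report-level data (duplicate removal,
    ATC mapping, restriction to polypharmacy reports), marginal and pair/triad
    co-reporting prevalences with observed-to-expected (O/E) ratios under an
    independence null, construction and export of the weighted undirected
    drug co-reporting network, community detection by Louvain modularity
    optimisation and by the leading-eigenvector method, demographic summary
    tables, sex- and age-stratified reruns, and a synthetic ICSR generator
    with planted co-prescription communities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    igraph,
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
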