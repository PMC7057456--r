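Package: routescore
Title: Route-Based Topological Pathway Analysis via Bayesian Network Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores activation and suppression of routes through signed
    gene-regulation pathways. Pathway topologies are read from KEGG KGML or
    signed edge-list files, simple-path routes are enumerated by depth-first
    search, and each route is scored against discretized expression and
    mutation observations using a chain-shaped Bayesian network whose
    conditional probability tables encode activation and inhibition logic.
    Pathway-level scores aggregate route consistency, statistical
    significance is quantified through a Poisson-binomial model of null
    route consistency, and the error-rate hyper-parameter is calibrated
    analytically from a binomial quantile bound on the null score
    distribution. Includes a synthetic fixture generator and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
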