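Package: hemiconn
Title: Hemispheric Segregation and Integration of Functional Brain Networks
Version: 1.0.0
Authors@R:
    person("Hemiconn", "Developers", email = "maintainers@hemiconn.dev",
           role = c("aut", "cre"))
Description: Analysis pipeline for hemisphere-level organization of
    resting-state functional connectivity on mirror-paired (homotopic)
    parcellations. Builds Fisher z-transformed connectivity matrices from
    parcellated BOLD time series, screens subjects by head motion (mean
    framewise displacement) and regions by temporal signal-to-noise ratio,
    detects mirror-symmetric functional networks with seeded Louvain
    modularity maximization plus consensus clustering across hemispheres,
    and computes per-network hemispheric statistics: inter-hemispheric
    segregation, homotopic (inter-hemispheric) integration, and
    intra-hemispheric integration via weighted participation coefficients.
    Age associations are assessed with partial Pearson correlations under
    Bonferroni or Benjamini-Hochberg correction. A synthetic cohort
    generator with block-structured covariance and planted aging effects
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
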