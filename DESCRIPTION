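Package: swarmcorr
Title: Correlation, Susceptibility and Interaction Range in Insect Swarms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for collective behaviour in disordered animal
    groups, built around 3D trajectories of midge swarms. Decomposes group
    motion into translation, optimal rotation and optimal dilatation modes,
    computes dimensionless velocity fluctuations, the connected spatial
    correlation function, the correlation length and the integrated
    correlation (susceptibility). Includes the two generative models used as
    references: a non-interacting harmonic swarm (independent Langevin
    particles in a harmonic trap) and a 3D Vicsek model with a central
    harmonic force, with density scans and finite-size scaling. A percolation
    analysis of the spatial point sets and permutation-based rank statistics
    combine into an estimate of the metric interaction range in body lengths.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
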