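Package: meioMC
Title: Monte Carlo Modelling of Meiotic Chromosome Organisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo sampling of spherically confined,
    discretised worm-like-chain models of meiotic chromosomes, with optional
    tethering of centromeres or telomeres to the nuclear envelope and
    von Mises-Fisher clustering forces directed at the spindle pole body.
    Provides ensemble analytics used to quantify homologue juxtaposition
    during the Rabl-to-bouquet transition: locus distance maps, allelic
    profiles, rank-score curves, telomere clouds, and two-sample condition
    comparisons, together with closed-form worm-like-chain oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
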