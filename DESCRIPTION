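Package: multiwebsim
Title: Dynamics of Multiplex Ecological Networks with Non-Trophic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the dynamics of multiplex ecological networks: an
    allometric bioenergetic food-web model (niche-model topology, Holling/Hill
    functional response, Beddington-DeAngelis predator interference) extended
    with six non-trophic interaction mechanisms (competition for space,
    predator interference, refuge provisioning, recruitment facilitation, and
    increases or decreases in mortality). Provides rule-based generators for
    the trophic and non-trophic network layers, an adaptive Runge-Kutta-
    Fehlberg integrator with extinction clamping, paired with/without
    ensemble experiments, and the summary statistics used to quantify the
    effect of non-trophic interactions on diversity, biomass, production and
    the biodiversity-ecosystem-functioning relationship.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
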