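Package: megabiota
Title: Metabolic Scaling Predictions for the Largest Plants and Animals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metabolic scaling theory applied to the megabiota, the largest
    trees and animals in an ecosystem. Provides closed-form and quadrature
    implementations of allometric extinction-risk scaling, truncated
    power-law size spectra with their total-biomass, total-flux and
    net-primary-productivity integrals, log-log power-law fitting (ordinary
    least squares and standardized major axis, with analytic or bootstrap
    confidence intervals), an allometric model of herbivore-mediated lateral
    nutrient diffusivity with size-threshold extinction scenarios, and a
    steady-state diffusion-loss solver for soil-nutrient fields on gridded
    domains. Synthetic-data generators emulate forest-plot size spectra,
    Pleistocene-like herbivore communities and basin-scale gridded domains
    so that every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
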