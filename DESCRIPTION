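Package: frontfish
Title: Fine-Scale Ocean Fronts and Acoustic Fish Concentration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the statistical association between fine-scale
    ocean fronts and mesopelagic fish concentration, together with a
    gradient-climbing model of fish aggregation. Includes a synthetic ocean
    generator (divergence-free mesoscale eddy fields, passively stirred sea
    surface temperature and chlorophyll, ship transects with a limiting-factor
    acoustic backscatter law), Lagrangian front diagnostics (particle advection,
    finite-size Lyapunov exponents, kilometric SST gradients, along-track
    colocation), acoustic transect processing (layer-averaged fish
    concentration, distance-binned acoustic units, solar day/night
    classification, polygon region masks), the statistical battery of the
    front-biomass analysis (threshold splits, Mann-Whitney and bootstrap
    difference-of-means tests, pinball-loss linear quantile regression,
    chlorophyll-gated regression), and a one-dimensional continuity-equation
    solver for gradient-climbing fish drift over tracer plateaus and
    strain-diffusion filaments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
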