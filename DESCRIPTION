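Package: atriumflow
Title: Post-Processing of Right-Atrium Hemodynamics on Sampled Flow Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative machinery for analysing blood flow in the right
    atrium and venae cavae on time-resolved velocity fields sampled on
    uniform Cartesian grids: Quemada shear-thinning blood rheology, the
    wall-adapting local eddy-viscosity (WALE) subgrid operator, resolved and
    subgrid turbulent kinetic energy, helicity, vorticity and wall-shear
    metrics with region- and scenario-wise averaging, an inlet flow-split
    scenario engine, venous morphometry statistics, and verification
    utilities (grid convergence index, spectral checks). Ships analytic and
    stochastic field generators so every pipeline stage is testable against
    closed-form oracles without a CFD solve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
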