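Package: stenoflow
Title: Virtual Translesional Pressure Ratios for Stenosed Renal Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of the translesional pressure ratio
    (Pd/Pa) across a renal artery stenosis by steady computational fluid
    dynamics. Generates parametric stenosed-vessel geometries with tortuous,
    ostially stenosed renal-like templates, builds boundary-fitted tetrahedral
    volume meshes with graded near-wall layers, solves the steady
    incompressible Navier-Stokes equations for Newtonian blood in a rigid
    lumen with plug inlet and peripheral-resistance outlet boundary
    conditions, and extracts the virtual Pd/Pa from area-averaged pressures
    on cross-sectional probe planes. Includes Bland-Altman agreement and
    diagnostic-accuracy statistics with exact binomial confidence intervals
    for validating virtual against invasively measured pressure ratios.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
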