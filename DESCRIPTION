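Package: thcdea
Title: Efficiency and Spatial Econometric Analysis of Health Resource Allocation Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for panel-data efficiency and spatial analysis of health
    resource allocation across regions. Implements non-oriented slacks-based
    measure (SBM) data envelopment analysis and its super-efficiency variant
    under variable returns to scale, the global-frontier Malmquist
    productivity index with its decomposition into efficiency change and
    technical change, global and local Moran spatial autocorrelation on
    contiguity weight matrices, and maximum-likelihood spatial panel models
    (spatial Durbin, spatial lag, spatial error) with two-way fixed effects,
    specification tests, and direct/indirect effect decomposition. Includes
    synthetic panel generators for validation and packaged reference tables
    for a 29-province, 10-year township health centre panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
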