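Package: follisim
Title: Kinetic Modelling of TEK-Driven Signalling in Ovarian Follicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary-differential-equation models of the
    TEK (Tie2) receptor signalling network that drives the Ras/ERK/MYC and
    PI3K/AKT/mTORC1 cascades during ovarian folliculogenesis. Provides a
    reaction-network representation with structural analyses (stoichiometric
    matrix, conserved moieties, validation), programmatic builders for the
    subordinate-follicle, dominant-follicle and dominant-follicle-plus-miRNA
    scenario models, stiff ODE integration via deSolve, SBML Level 3 import
    and export, and kinetic readout analysis (peak times, amplitudes,
    time-to-half-maximum, cross-scenario orderings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
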