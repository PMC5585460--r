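Package: coranalog
Title: Electrical Analog Modelling of Coronary Hemodynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lumped-parameter (zero-dimensional) modelling of the coronary
    circulation by the electronic-hydraulic analogy: coronary trees with
    stenoses, collateral channels and Leaman-weighted myocardial beds are
    compiled to DC resistor networks, solved by modified nodal analysis, and
    interrogated for fractional-flow-reserve (FFR) analogs, territory flows,
    the effect of percutaneous coronary intervention, serial-lesion
    interaction and coronary steal.  Ships a calibrated reference teaching
    case (serial LAD stenoses with a collateralized right coronary chronic
    total occlusion), a declarative YAML/JSON model format, SPICE netlist
    export, scenario tables and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
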