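Package: endonet
Type: Package
Title: Mechanistic Modeling of the Endothelial VEGF and Angiopoietin-Tie Signaling Network
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained, rule-derived ordinary differential equation model of
    the coupled VEGF/VEGFR2 and angiopoietin/Tie2 signaling network of endothelial
    cells, including receptor trafficking, ligand-induced Tie2 clustering, Tie2
    ectodomain shedding, Weibel-Palade-body Ang2 release, and the shared
    PI3K/Akt, Src/VE-cadherin, calcium and Erk downstream network. Provides a
    stiff simulator for stimulation protocols, pattern-search calibration to
    normalized time-course and dose-response data, variance-based (Sobol) global
    sensitivity analysis with bootstrap confidence intervals, reproducible
    in-silico experiments on chronic versus acute Ang1 vascular protection and
    inhibitor-Ang1 combination grids, a synthetic-data generator for
    calibration fixtures, and SBML/CSV/YAML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
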