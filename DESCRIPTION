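Package: graftnet
Title: Multiscale Gene-Cluster Network Modeling of Vein Graft Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates and calibrates a multiscale model of early vein graft
    adaptation that couples shear-stress-driven intimal growth to the dynamics
    of five gene-expression clusters organized as interconnected ordinary
    differential equation networks. Provides the three-stage genetic-algorithm
    calibration chain (cluster-network parameters with a knockdown-stability
    penalty, signed cluster weights under an L1 constraint, and unit-scaling
    factors fitted to intimal thickness), an in-silico gene-therapy screening
    procedure over constant single- and paired-cluster modulations with
    viability constraints and sensitivity analysis, and a synthetic-data
    generator with known ground truth emulating a rabbit vein graft study
    design (7 sampling times from implantation to 28 days, ligated low-flow
    scenario).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
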