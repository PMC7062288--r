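Package: gliosim
Title: Hybrid Multiscale Agent-Based Simulation of PDGF-Driven Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growth-factor driven glioblastoma as a hybrid
    discrete-continuum system: individual tumor cells are off-lattice agents
    with heritable proliferation and migration potentials, modulated by a
    platelet-derived growth factor (PDGF) field that diffuses and decays on a
    fine hexagonal lattice inside a gray/white-matter brain domain. Includes
    stop-and-go persistent random-walk migration with white-matter anisotropy,
    density-dependent quiescence, recruitment of resident progenitor cells,
    anti-proliferative and anti-migratory treatment simulation, imaging- and
    cell-scale metrics (tumor diameter, core/rim, Ki-67 proxy, phenotype
    statistics), virtual cell tracking with run/stop segmentation, and a
    hybrid genetic-algorithm/random-sampling calibration to multiscale
    reference data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
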