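Package: qdfret
Title: FRET Photophysics of Quantum-Dot/Dye/DNA-Origami Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Photophysical analysis toolkit for valence-controlled
    quantum-dot (QD) / dye / DNA-origami assemblies. Computes spectral
    overlap integrals and Forster distances from emission and molar
    absorptivity spectra, single-pair and multi-acceptor FRET
    efficiencies with the inverse problems (acceptor count and
    donor-acceptor distance from measured efficiency), three-node
    concentric multi-step FRET networks with competitive and sequential
    quenching pathways, multi-exponential TCSPC lifetime fitting with
    amplitude-weighted mean lifetimes, absorbance spectral unmixing for
    dye/QD stoichiometry, idealized wireframe-polyhedron scaffold
    geometry, and a self-avoiding-walk polymer mapping from radius of
    gyration to Kuhn and persistence lengths. A synthetic-data module
    generates spectra, photon-count decay histograms with Poisson noise,
    FRET observables, and bond-angle ensembles with known ground truth so
    every stage of the pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
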