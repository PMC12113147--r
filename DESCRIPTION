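Package: lnpsaxs
Title: Core-Triple-Shell SAXS Modelling of Lipid Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and least-squares fitting of 1D small-angle
    X-ray scattering (SAXS) curves from lipid nanoparticles (LNPs) using a
    polydisperse spherical core-triple-shell form factor (inner lipid layer,
    hydrophilic headgroup layer, PEG corona) with a Gaussian core-radius size
    distribution integrated by fixed Gauss-Legendre quadrature, plus an
    additive Gaussian quasi-Bragg peak describing the quasi-periodic packing
    of mRNA-ionizable-lipid assemblies. Includes synthetic-curve generation
    and parameter sweeps, parameter-recovery experiments, multi-frame
    similarity QC and averaging, plain-text reduced-SAXS I/O, derived
    structural metrics (polydispersity ratio, repeat distance), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
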