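Package: mconiom
Title: Multicenter n-Layer Subtractive ONIOM with mRRHO Thermochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tree-structured multicenter n-layer subtractive ONIOM
    (mechanical embedding) for molecular systems: fragment partitioning
    with hydrogen link-atom capping placed by covalent-radius ratios,
    recursive assembly of composite energies, gradients and Hessians over
    the layer dependency tree with Jacobian projection of fragment
    derivatives into the real-system basis, a pluggable energy-calculator
    contract with built-in analytic toy potentials, normal-mode analysis
    on composite Hessians, and modified rigid-rotor harmonic-oscillator
    (mRRHO) free energies with low-frequency rovibrational entropy
    interpolation for supramolecular reaction free energies and their
    temperature dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
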