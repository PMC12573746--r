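Package: anharmvoa
Title: Anharmonic Vibrational Optical Activity Spectra by Generalized
    Second-Order Vibrational Perturbation Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts a quartic vibrational force field and electric/magnetic
    property surfaces (dipole, magnetic dipole, polarizability, G' and A
    tensors) into anharmonic IR, VCD, Raman and ROA spectra using generalized
    second-order vibrational perturbation theory (GVPT2).  Fermi and
    Darling-Dennison resonances are detected from energy- and intensity-based
    criteria, removed from the perturbative sums and reintroduced through a
    variational step.  Includes a synthetic model-system generator with
    controlled anharmonicity, contrived near-resonances and enantiomer mirror
    images, a two-step finite-difference module for cubic/quartic force
    constants and higher property derivatives, a brute-force variational
    solver in a harmonic-oscillator product basis that serves as an
    independent oracle for systems of up to three modes, Lorentzian band
    convolution, and a spectral similarity statistic with optimal frequency
    scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
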