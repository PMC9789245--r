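Package: vestifem
Title: Fourier Finite-Element Simulation of Vestibular Nerve Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Volume-conductor simulation of electrical stimulation of the
    vestibular system with frequency-dependent complex tissue admittivity.
    Implements Cole-Cole dielectric dispersion models for inner-ear tissues,
    charge-balanced biphasic stimulus waveforms and their discrete Fourier
    transforms, a labeled tetrahedral phantom generator with spherical
    stimulation electrodes and anisotropic nerve bundles, a first-order
    finite-element solver for the complex-admittivity Laplace equation with
    an instrumental electrode boundary model (double-layer capacitance and
    scar-tissue resistance) and stimulation power limiting, a spatially
    extended nonlinear node (SENN) myelinated-fiber model with binary-search
    threshold estimation, and recruitment-curve / ROC / AUC selectivity
    analysis of multi-branch nerve activation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
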