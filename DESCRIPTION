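Package: espec
Title: Quantum-Classical Simulation and Trajectory Quantization for
    Hydrated-Electron Absorption Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying nuclear quantum effects on the optical
    absorption spectrum of excess electrons in water. Implements a mixed
    quantum-classical molecular dynamics engine (one-electron
    pseudopotential on a cubic grid with a block Lanczos eigensolver,
    flexible simple point-charge water, Hellmann-Feynman coupling),
    post-hoc quantization of classical nuclear trajectories by
    convolution with a harmonic-oscillator-weighted filter kernel
    (generalized smoothed trajectory analysis), ensemble assembly of
    absorption spectra in the slow-modulation limit, Gaussian sub-band
    fitting, spectral moment statistics with bootstrap confidence
    intervals, and structural observables (radial distribution
    functions, OH-distance distributions, OH bond-scaling transforms).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml, jsonlite, minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
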