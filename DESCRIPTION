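Package: escat
Title: Electro-Scattering Antenna Modeling and Electro-Optic Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and analysis tools for electrochromic polymer
    scattering antennas used as wireless optical voltage sensors.
    Implements voltage-dependent PEDOT:PSS complex permittivity
    (Drude, Lorentz and Tauc-Lorentz oscillator models with linear
    doping-level interpolation), Mie scattering cross sections of a
    volume-equivalent sphere surrogate, the series RC equivalent
    circuit of the antenna-electrolyte interface with impedance
    spectra and analytic step responses, a digital twin composing
    circuit dynamics with a sigmoid scattering transfer, a Z-score
    time-lapse image analysis pipeline (registration, segmentation,
    sensitivity, noise, SNR, limit of detection, time constants), a
    Luo-Rudy 1991 cardiomyocyte action-potential model coupled to the
    cell-sensor seal/junctional interface circuit, and ground-truthed
    synthetic camera stacks and impedance spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
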