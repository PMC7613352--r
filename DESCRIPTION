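Package: proxsif
Title: Proximal-Sensing Retrieval of Sun-Induced Chlorophyll Fluorescence
    with Oxygen Transmittance Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and retrieval toolkit for tower-based (proximal
    sensing) measurements of sun-induced chlorophyll fluorescence (SIF) in
    the O2-A and O2-B telluric absorption bands. Provides a synthetic
    line-by-line oxygen transmittance engine with pressure and temperature
    scaling, the Pierluisi empirical band model, Gaussian instrument
    spectral response convolution, the Fraunhofer Line Discriminator family
    (FLD, 3FLD, iFLD) and Spectral Fitting Method (SFM) retrievals, their
    O2-compensated variants, and a convolution-consistent SFM that fits the
    atmosphere from at-sensor irradiance and convolves the forward model
    inside the minimisation. Includes scripted error sweeps over sensor
    heights and spectral resolutions and a seasonal temperature/pressure
    analysis of the oxygen band depth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
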