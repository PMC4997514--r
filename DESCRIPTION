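Package: vapormix
Title: Well-Mixed Indoor Air Modelling of E-Vapor Constituents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Transient single-zone (well-mixed) simulation of indoor air
    concentrations of e-vapor constituents (nicotine, propylene glycol,
    glycerol, water) released into a ventilated space.  At every time step
    the released aerosol is re-partitioned between droplet and vapor phase
    by solving a multicomponent Raoult-type vapor-liquid equilibrium
    system, and a first-order air-exchange mass balance removes material
    with the ventilation air.  Ships Antoine-type saturation-pressure
    models for the four constituents, built-in validation scenarios
    (machine-generated releases into a 39 m3 room and exhaled-breath
    sources in a 113 m3 exposure chamber), sensitivity variants, and an
    independent brute-force partitioning oracle used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
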