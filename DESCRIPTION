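Package: cudosim
Title: Cellular Dosimetry and Biological Effectiveness of Cu-64 Radiopharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo estimation of the absorbed dose per decay
    delivered by Cu-64 emissions (beta particles, Auger electrons, characteristic
    X-rays) to water spheres of varying volume, together with the downstream
    analysis chain: coumarin-3-carboxylic-acid (C3CA) chemical dosimetry via
    hydroxyl-radical G-values, Co-60-equivalent dose reconstruction, and
    D10/RBE estimation for clonogenic survival. Ships versioned electron
    stopping-power and photon attenuation tables for liquid water, a
    configurable Cu-64 decay scheme sampler (Fermi beta spectra, Auger/X-ray
    relaxation), a condensed-history electron transport with per-component
    dose tallies, and synthetic-data generators for every measurement the
    analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
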