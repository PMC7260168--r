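Package: escrtube
Title: Mechanics of ESCRT-III-Scaffolded Helical Membrane Tubes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Continuum-mechanics analysis of helical ("corkscrew") membrane
    tubes scaffolded by bundled ESCRT-III (Snf7/Vps24/Vps2) filaments.
    Implements the differential geometry of helices and of circular
    cross-section tubes (canal surfaces) around them; Helfrich bending plus
    tension energies of straight and helical membrane tubes; a rigid-scaffold
    model yielding the helical-versus-straight phase diagram, the critical
    tube radius and a lower bound on the polar-versus-equatorial
    membrane-binding energy difference; and a deformable-filament model
    (Kirchhoff rods with bending and torsional persistence lengths and
    helical rest shapes) whose stationarity conditions at an observed tube
    geometry are inverted to infer membrane tension, torsional persistence
    length and the binding energy difference. Includes generators for
    synthetic geometry measurements and forward-simulated equilibria,
    bootstrap uncertainty propagation, and reproducible pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
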