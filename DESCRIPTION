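Package: leafdev
Title: Self-Organizing Simulation of Leaf Margin Growth, Venation and Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic planar simulator of leaf development in which leaf
    form emerges from a feedback loop among margin patterning, vein insertion
    and vein-driven growth. Convergence points are inserted on the growing
    margin by a Hofmeister-type arc-length spacing rule modulated by abstract
    morphogens; each new convergence point is connected to the existing
    vasculature by a vein route that minimizes a transport-resistance
    functional (yielding a constant branching angle arccos(v/b)); veins
    elongate according to a piecewise-linear relative elementary growth rate
    profile and carry the margin with them; geometric fairing ("webbing")
    smooths the margin between vein tips. The package provides the full
    simulation loop, preset configurations reproducing a repertoire of leaf
    forms (simple, toothed, lobed, palmate, pinnately compound), a conforming
    triangle mesh of the blade, shape descriptors for morphospace sweeps, and
    SVG/JSON snapshot output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    Matrix,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
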