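Package: notumpattern
Title: Lateral-Inhibition Dynamics and Bristle Patterning on Disordered
    Cell Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates Notch-mediated lateral inhibition during sensory
    bristle patterning in the fly dorsal thorax.  Each cell of a
    disordered periodic lattice carries a bistable scalar state (proneural
    activity) driven by a sigmoidal balance of self-activation and
    inhibitory signalling; the inhibitory signal combines a time-dependent
    extrinsic gradient (the early negative template and the late flank
    sources) with distance-weighted ligand activity from surrounding
    cells.  Includes fate calling and spacing statistics for the
    resulting sensory-organ-precursor patterns, mutant-like parameter
    regimes, a quantification pipeline for nuclear reporter intensities
    binned by distance to a stripe centerline, and seeded synthetic-data
    generators for all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
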