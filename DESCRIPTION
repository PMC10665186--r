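Package: sarcgeom
Title: Geometric Analysis of Cardiac Sarcomere Filament Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantitative geometry for cryo-electron-tomography models of the
    cardiac thick filament. Provides crown-pose quantification (cylinder axis
    fitting, interacting-heads-motif landmark triangles, Euler angles and
    cylindrical coordinates, crown classification and cylinder unrolling),
    coiled-coil midline tracing with the sinuosity / sinusoidal-compression
    statistic, filament-aware particle-table bookkeeping (resampling, axial
    shift propagation, duplicate removal, point-group and helical symmetry
    expansion), axial periodicity spectra with pixel-size calibration, thick-
    to-thin link-angle measurement, and a synthetic sarcomere generator that
    produces ground-truth lattices so every analysis stage is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
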