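Package: braggkit
Title: Direct-Summation Structure Factors, Fringe Simulation and Bragg
    Spotfinding for Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for small-crystallite diffraction simulation and
    high-throughput diffraction-image triage.  Computes macromolecular
    structure factors by direct summation over unit cells, space-group
    operators and scatterers, at integer or fractional Miller indices and
    in selectable (32- or 64-bit) floating-point precision, with an
    FFT-based electron-density reference for accuracy cross-checks and a
    finite-crystal Laue interference model that renders fringe patterns.
    Also provides a Bragg spotfinder for pixel-array detector frames
    (robust per-tile background classification, connected-component spot
    identification, ice/powder-ring rejection, spot-quality heuristics and
    per-image quality statistics), sliding-window hit-rate monitoring for
    serial femtosecond crystallography streams, a two-lattice spot-overlap
    classifier, and a seeded synthetic frame generator with SMV image
    input/output used as the test bed.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
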