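Package: stedsense
Title: Binary Phase Masks for SLM-STED Alignment and Modal Aberration Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for optimizing spatial-light-modulator (SLM) based STED
    microscopes with binary phase masks. Provides a vectorial Richards-Wolf
    focal-field simulator (FFT evaluation of the Debye integrals with a
    direct-quadrature oracle), generators for the alignment and
    aberration-sensing masks (half-space, four-segments, six-segments,
    split-bullseye, vortex/fork), central-intensity sensing scans with a
    closed-loop modal wavefront-sensing protocol for astigmatism, coma and
    trefoil, doughnut quality metrics, 2D-Lorentzian bead-image analysis and
    the STED resolution-law fit, plus SLM bitmap/TIFF/CSV/JSON input-output
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
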