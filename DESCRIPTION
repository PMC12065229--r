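Package: cafri
Title: Carbon Footprint Reduction Index for Analytical Methods
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Carbon Footprint Reduction Index (CaFRI), a
    rubric-based greenness metric that scores the carbon-footprint
    performance of analytical laboratory procedures across 19 criteria in
    8 categories (energy, CO2 emission, storage, transportation,
    personnel, waste, recycling, reagents/solvents). Provides the fixed
    scoring rubric, answer-sheet validation and scoring with traffic-light
    colors, instrument power estimation from a bundled technique table,
    electricity emission-factor banding with country-level grid-intensity
    defaults, a foot-shaped SVG result pictogram, markdown/HTML reports,
    bundled case-study fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
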