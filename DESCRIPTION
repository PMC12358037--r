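Package: florivis
Title: Pollinator Vision Modelling of Floral Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how flowers are perceived by insect
    pollinators from UV-VIS reflectance spectra (300-700 nm). Provides
    reflectance-spectrum processing (reading, resampling, local-regression
    smoothing, negative-value correction, aggregation), receptor quantum
    catches with von Kries chromatic adaptation, colour loci in the
    honeybee colour hexagon and the tetravariant fly colour space,
    chromatic and achromatic contrasts with discriminability-threshold
    flags, spectral marker-point detection with MAD/minAD fit metrics
    against discrimination optima, simulation-based phylogenetic ANOVA
    with Holm-adjusted post hoc comparisons, and a pigment-based
    synthetic-spectrum generator so the whole workflow can be exercised
    and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
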