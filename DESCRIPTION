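Package: tetrixmra
Title: Multivariate Ratio Analysis for Morphometric Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for species delimitation from linear distance
    measurements, built around multivariate ratio analysis (MRA) as applied
    to the two wing morphs of the Tetrix bipunctata pygmy grasshopper
    complex.  Provides isometric size (isosize, the geometric mean of all
    measurements), shape principal component analysis on log shape values,
    PCA ratio spectra with bootstrap confidence intervals, a best-ratio
    extractor for two groups, allometry and allometric-scaling diagnostics
    via ANCOVA, chained-equations imputation of missing measurements, the
    standard hind-wing/tegmen ratio classifier, microhabitat niche ANOVAs,
    and syntopy detection with altitudinal profiles from locality records.
    A synthetic-data generator emulating the two-morph structure makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
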