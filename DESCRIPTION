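Package: allodev
Title: Phylogenetically Informed Allometric Deviation Analysis for Brain
    Structure Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether a target species deviates from the allometric
    scaling expected from a set of reference species. Fits log-log
    regressions of brain structure volume on cerebral hemisphere volume
    (with part-whole correction) through reference species only, gates the
    fit between ordinary least squares and Felsenstein independent
    contrasts by maximum-likelihood estimation of Pagel's lambda, builds
    95% prediction intervals mapped back to arithmetic volume space, and
    classifies the target species as above, within, or below expectation,
    reporting percent residuals. Includes a seeded synthetic-data
    generator for trees and specimen tables, calibration experiments
    (interval coverage, lambda and slope recovery), outlier-taxon
    screening, and packaged hominoid and anthropoid volumetric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
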