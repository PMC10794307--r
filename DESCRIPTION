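Package: discmorph
Title: Optic Disc Morphometry and Parapapillary Vessel Density Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated optic nerve head morphometry and regional vessel
    density analysis for en-face retinal imaging. Computes disc tilt ratio
    and signed rotation degree from contoured disc borders, extracts
    parapapillary quadrant vessel densities from OCT angiography maps over
    the 1-3 mm annulus, derives ocular indices (relative lens position,
    mean ocular perfusion pressure, axial-length grouping), and runs the
    cohort association pipeline (group summaries, univariate screening,
    multivariate logistic and stepwise linear regression). Includes a fully
    seeded synthetic eye and cohort generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
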