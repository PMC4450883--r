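Package: mahinge
Title: Mitral Annulus Hinge-Point Detection in Echocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the two hinge points of the mitral annulus (the septal
    and lateral leaflet attachment points) in 2D four-chamber
    echocardiographic frames. A sparse local-context feature samples
    mean-filtered gray values along eight directions at fixed radii; a
    histogram-intersection-kernel support vector machine classifies every
    pixel, using an exact table-based evaluation of the additive kernel that
    reduces per-pixel cost from O(m*n) to O(n*log m); a weighted density
    field with an adaptive threshold and a two-centre K-means step refines
    the candidate set into the two landmark coordinates. A synthetic
    echo-phantom generator with known ground truth makes the full pipeline
    trainable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    kernlab,
    jsonlite,
    png,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
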