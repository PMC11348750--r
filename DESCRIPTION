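Package: rootwhorl
Title: Whorl and Soil-Line Phenotyping on Root-Crown Curve Skeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects whorls of nodal roots and estimates the soil line on
    curve skeletons of excavated maize root crowns, and computes the
    associated fine-grained root-architecture traits.  Candidate root
    emergence paths are found by constrained shortest-path search on the
    skeleton graph, simplified with a forced-first-split
    Ramer-Douglas-Peucker pass, scored by their turning geometry, and
    grouped into whorls with a threshold-persistent mean-shift clustering.
    The soil line is located by fitting a Gaussian to the depth profile of
    lateral-root length density.  A synthetic root-crown generator with
    full ground truth supports end-to-end validation, and a command-line
    driver runs the whole pipeline on skeleton files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
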