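Package: sdcomm
Title: Hyperbolic Random Graphs with Soft Communities on D-Spheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generators and analytics for latent-space random graphs on the
    D-sphere (the S^D model, equivalent to random graphs in (D+1)-dimensional
    hyperbolic space). Provides uniform and clustered (soft-community) sampling
    of angular coordinates, Pareto latent degrees with mean-degree calibration,
    closed-form and quadrature-based distributions of the angular distance
    between connected nodes, hyperspherical nearest-neighbor counts, and
    community block-matrix diagnostics (stable rank, Shannon entropy, and
    community degrees), together with a sigma-sweep experiment runner that
    contrasts community structure on the circle (D = 1) with the sphere
    (D = 2).
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
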