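Package: saltpulse
Title: Split-Plot PERMANOVA and Recovery Metrics for Disturbed Soil
    Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distance-based analysis of repeated-measures microbiome
    disturbance experiments laid out as randomized complete blocks with
    plots sampled through time. Implements restricted-permutation
    PERMANOVA with a whole-plot-error pseudo-F for split-plot designs,
    paired day-versus-baseline recovery tests, multivariate dispersion
    with negative-eigenvalue correction, Bray-Curtis
    resistance/resilience trajectories, similarity-percentage (SIMPER)
    taxon ranking, and partial distance-based redundancy analysis, plus
    a Dirichlet-multinomial synthetic-community generator emulating a
    blocked salinity-pulse field experiment so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
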