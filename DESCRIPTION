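Package: stemspat
Title: Spatial Pattern Analysis of Fully Mapped Forest Stem Plots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Census summarization and spatial point-pattern analysis of fully
    mapped forest dynamics plots. Implements Ripley's K and L functions
    (univariate and bivariate) with analytic isotropic edge correction on
    rectangular windows, Monte Carlo null models (complete spatial randomness
    and population independence via toroidal shifts), the Loosmore-Ford
    goodness-of-fit test with Bonferroni control, point-process simulators
    spanning a uniform-random-clustered gradient (simple sequential
    inhibition, Matern cluster thinned to a fixed count, jitter), a
    permutation experiment measuring how the spatial pattern of
    large-diameter trees drives quadrat-scale heterogeneity of basal area
    (coefficient of variation and skewness across quadrat grains), and a
    synthetic stem-map generator emulating an old-growth Pseudotsuga/Tsuga
    forest for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    ggplot2
Config/testthat/edition: 3
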