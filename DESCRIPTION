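Package: phagoglia
Title: Volumetric Quantification of Glial Phagocytosis and Microglial
    Morphology in 3D Fluorescence Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify glial phagocytosis of dopaminergic (TH+)
    signal from calibrated multi-channel confocal z-stacks. Segments TH,
    Iba1 and GFAP channels into 3D particles with a minimum-size filter,
    measures marker volumes in cubic micrometres and the percentage of TH+
    volume engulfed inside glial masks, profiles microglial ramification
    with 3D Sholl analysis, classifies microglia into ramified,
    hypertrophic and bushy morphologies with explicit threshold rules, and
    runs normality-routed group statistics (Student/Welch t,
    Mann-Whitney U, one-way ANOVA, Kruskal-Wallis with Dunn post hoc,
    two-way ANOVA with Bonferroni post hoc) reporting means with 95%
    confidence intervals. Ships a ground-truthed synthetic confocal-stack
    simulator (parametric glial cells, controlled engulfed fraction,
    Gaussian PSF blur, Poisson photon noise) so the entire pipeline is
    testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
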