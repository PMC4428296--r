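Package: connmature
Title: Developmental Trajectories of Weighted Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of age- and sex-related change in weighted structural
    brain networks built from streamline tractography. Provides weighted
    graph metrics (density, global and local efficiency, modularity,
    within-module strength, participation coefficient) with normalization
    against degree- and strength-preserving rewired null networks,
    subject-wise edge taxonomies (thick/thin, short/long, intra/inter-module,
    intra/inter-hemisphere), general-linear-model trajectory fitting with
    nested model selection, repeated-measures slope contrasts, chi-squared
    tests of preferential streamline detachment, FDR-controlled edgewise and
    nodal analyses with false-coverage-rate adjusted confidence intervals,
    and a synthetic cohort generator emulating the statistical structure of
    a cross-sectional developmental connectome study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
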