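Package: sedemodt
Title: SeDeM-ODT Expert-System Scoring and Orally Disintegrating Tablet
    Formulation Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SeDeM and SeDeM-ODT expert systems for judging
    the suitability of powders and powder blends for direct compression:
    conversion of experimental rheology parameters (bulk/tapped density,
    Carr index, Hausner ratio, cohesion index, angle of repose, flow time,
    hygroscopicity, fines, homogeneity and disintegration measures) to
    0-10 radius values, incidence-factor means, the parameter profile
    index, the index of good compressibility (and bucodispersibility),
    radar-diagram geometry and the corrective-excipient dose equation.
    Also provides the surrounding tablet-development workflow: rotatable
    central composite designs and tablet composition arithmetic,
    response-surface fitting with ANOVA and adequate-precision
    diagnostics, dissolution release-kinetics model fitting (first-order,
    Higuchi, Hixson-Crowell, Weibull) with best-model selection,
    ICH-style shelf-life estimation from stability series, compendial
    quality-attribute limit checks, and seed-controlled synthetic data
    generators so the full pipeline is testable without laboratory data.
    Reference data from a flurbiprofen orally disintegrating tablet
    development campaign are bundled as worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
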