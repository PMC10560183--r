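Package: facemotion
Title: Kinematic and Statistical Analysis of 4D Facial Expression Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing corresponded 3D mesh sequences of facial
    expressions captured by 4D stereophotogrammetry. Reads PLY/OBJ mesh
    sequences with vertex-wise correspondence, trims recordings to
    expression clips (rest to maximum), and computes four kinematic
    parameters per clip: magnitude and symmetry of landmark displacement,
    Procrustes shape change of the lower face, and time to peak. A cohort
    statistics layer fits linear mixed-effects models with estimated
    marginal means, paired Wilcoxon sensitivity tests, multivariable linear
    models of surgical movement covariates, and two-way intraclass
    correlation coefficients for method-error analysis. A synthetic 4D
    face-motion generator produces corresponded mesh sequences and full
    cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
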