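Package: sceneGLMM
Title: Grid-Based Evaluation of Saliency Models with Generalized Linear
    Mixed Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates how well computational saliency maps predict human
    fixation selection in naturalistic scenes above and beyond the central
    fixation bias. Scenes are parcellated into regular grids of patches;
    per-patch mean saliency and a family of distance-to-center predictors
    (Euclidean, Gaussian, taxicab; isotropic, aspect-ratio and anisotropic
    variants) are attached to a long-format observation matrix of binary
    fixated indicators and fixation counts, which is analysed with binomial
    or Poisson generalized linear mixed models with crossed subject and
    scene-item random effects. Includes random-effects model selection
    tools (maximal, zero-correlation and intercept-only structures;
    likelihood-ratio tests, AIC/BIC, parameter bookkeeping), marginal and
    conditional R-squared, conditional-mode prediction intervals,
    saliency-model comparison via treatment-coded map factors, and a
    synthetic-data generator with controllable photographer bias for
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    Matrix,
    data.table,
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite,
    numDeriv
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'centralbias.R'
    'regions.R'
    'fixations.R'
    'glmm-spec.R'
    'glmm-fit.R'
    'obsmatrix.R'
    'synthetic.R'
    'pipeline.R'
    'sceneGLMM-package.R'
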