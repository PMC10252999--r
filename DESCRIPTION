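Package: vesselIQ
Title: Objective and Subjective Image Quality Assessment for Coronary CT
    Angiography Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image-quality analysis for coronary CT angiography
    reconstruction grids: region-of-interest attenuation, image noise and
    contrast-to-noise ratio in Hounsfield units; vessel border sharpness via
    bounded nonlinear least-squares fitting of a double-sigmoid edge model to
    attenuation profiles extracted perpendicular to the vessel wall; and the
    accompanying statistical comparison layer (one-way ANOVA with Tukey HSD,
    tie-corrected Kruskal-Wallis on Likert ratings, two-way random-effects
    intraclass correlation with qualitative agreement bins). Includes a
    synthetic vessel-phantom generator with kernel-dependent Gaussian
    point-spread functions and noise emulating a 3-kernel x 4-sharpness-level
    reconstruction design, plus a latent-quality generator for two-rater
    ordinal rating tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'kernels.R'
    'volume.R'
    'io.R'
    'phantom.R'
    'ratings.R'
    'roi.R'
    'sigmoid.R'
    'stats.R'
    'pipeline.R'
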