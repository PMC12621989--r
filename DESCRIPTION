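Package: wmasym
Title: Lifespan Normative Charts of White Matter Tract Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify hemispheric asymmetry of bilateral white
    matter tracts and chart how it changes across the lifespan. Computes
    the laterality index LI = (R - L)/(R + L) from paired left/right tract
    features (diffusion-tensor microstructure and tract macrostructure),
    fits age-varying Gaussian location-scale normative models in which both
    the median and the standard deviation of LI are smooth fractional
    polynomial functions of age with sex and study-cohort terms, selects
    smooth terms by BIC, and generates dense-age centile charts. Derived
    lifespan summaries include milestone-age asymmetry tables, model-based
    rightward-prevalence estimates, lateralization reversal (zero-crossing)
    detection, and mean slopes of the absolute median laterality within
    developmental and aging windows. Includes a multi-cohort synthetic data
    generator with known ground truth for end-to-end validation, and a
    scriptable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mgcv
Config/testthat/edition: 3
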