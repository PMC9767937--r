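Package: prfrecon
Title: Population Receptive Field Mapping and Visual Field Reconstruction
    with Simulated Scotomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how glaucomatous visual field defects are expressed
    in visual cortex with functional MRI. Converts perimetric sensitivity
    deviations (dB) into contrast-attenuation masks for simulated scotomas,
    generates drifting-bar retinotopy aperture movies, forward-simulates
    voxelwise BOLD responses through 2-D Gaussian population receptive fields
    (pRFs), estimates pRFs by grid search with local refinement (full-field and
    scotoma-field variants) as well as by dense micro-probing, reconstructs
    visual-field sensitivity maps by back-projection of pRF sampling density,
    classifies them against a normative control group with percentile deviation
    maps, and provides the pair-versus-baseline deviation-rank statistics and
    mixed-effects severity correlations used for group inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
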