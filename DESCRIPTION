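Package: dynFET
Title: Dynamic [18F]FET-PET Evaluation with Attenuation-Correction Bias
    Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the dynamic evaluation of [18F]FET brain PET studies:
    threshold-based region-growing lesion segmentation (relative-to-maximum
    and tissue-to-background definitions, fixed spherical volumes),
    time-activity-curve extraction, time-to-peak and tissue-to-background
    ratio computation, and rule-based categorisation of uptake curves into
    the established two- and three-class pattern schemes. A synthetic 4D
    brain phantom generator emulates 40-minute dynamic acquisitions with
    configurable lesion kinetics, physiological-uptake confounders,
    frame-duration-dependent noise, and time-independent multiplicative
    bias fields standing in for MRI-based attenuation-correction error, so
    that the sensitivity of curve categorisation to the attenuation
    correction can be studied end to end. A comparison harness tabulates
    pattern, time-to-peak, ratio and volume changes of each attenuation
    variant against a designated reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'frame-schedule.R'
    'geometry.R'
    'images.R'
    'nifti-io.R'
    'kinetic-models.R'
    'bias-field.R'
    'phantom.R'
    'segmentation.R'
    'kinetics.R'
    'comparison.R'
    'pipeline.R'
    'experiments.R'
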