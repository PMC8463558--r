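Package: cardioquant
Title: Quantitative Histology, Optical Mapping and ECG Analyses for
    Cardiac Radiotherapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of three quantitative
    pipelines used in cardiac radiotherapy research: whole-slide Masson
    trichrome fibrosis quantification (equally spaced tile sampling, SLIC
    superpixel preprocessing, L*a*b* K-means colour palette training and
    nearest-centroid pixel classification, and the collagen fibrosis
    fraction), optical-mapping electrophysiology metrics (activation maps
    from the maximum voltage derivative, longitudinal and transverse
    conduction velocity by ray regression from the stimulation site,
    action potential duration at 80 percent repolarization, and the
    effective refractory period from S1-S2 pacing), and murine/human ECG
    interval measurement (beat detection and averaging, the S-wave
    isoelectric-crossing QRS-end rule that excludes the murine J wave,
    robust QRS-shortening classification, and an exact paired Wilcoxon
    signed-rank comparison). Synthetic-data generators with known ground
    truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
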