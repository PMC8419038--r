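Package: octnirf
Title: Quantification of Intravascular OCT-NIRF Plaque Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of dual-modal intravascular optical
    coherence tomography / near-infrared fluorescence (OCT-NIRF) pullbacks:
    automated lumen contour segmentation on polar frames, distance-dependent
    fluorescence decay compensation against a pre-determined calibration
    curve, plaque target-to-background ratio (pTBR) statistics, landmark-based
    serial frame matching with tertile stratification of treatment response,
    ex vivo fluorescence reflectance imaging co-registration, positive-area
    scoring of stained histology sections, and biexponential blood-clearance
    fitting. Ships a synthetic-data generator that produces every input with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
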