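Package: gravitrace
Title: Calcium Activity of Neuronal Networks Across Parabolic-Flight Gravity Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous calcium activity of 2D neuronal
    networks imaged during parabolic flights. Models the parabola's gravity
    phases (1 g, 1.8 g, 0 g) as a labeled time axis, removes micron-scale
    rigid jitter with Lucas-Kanade feature tracking, extracts DF/F calcium
    traces from activity-based ROIs, detects transient peaks and estimates
    per-phase oscillation periods, computes field-level period ratios (alpha)
    and constitutive/triggered network classification, and counts viable
    neurons and astrocytes from nuclei masks via ring-shaped somatic ROIs.
    A synthetic movie generator with full ground truth makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
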