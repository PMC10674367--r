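Package: gaitfluct
Title: Fluctuation Indices of Whole-Body Gait Dynamics from Markerless Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the fractal temporal structure of whole-body movement
    during walking from markerless motion-capture keypoint streams. For each of 26
    body points the per-frame Euclidean distance to the navel is reduced to a
    "fluctuation index": the ordinary-least-squares slope of log power spectral
    density against log frequency over a 128-frame window. Includes a colored-noise
    gait simulator with an exact-recovery spectral synthesis mode, cohort-level
    one-way ANOVA with Tukey HSD pairwise comparisons, a packaged reference table of
    published group means for iNPH, Parkinson's disease and control cohorts, and a
    reproducible simulate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
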