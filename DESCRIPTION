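Package: shuttlebox
Title: Head Kinematics, Fiber Photometry and Signaled Avoidance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for cued (signaled) active-avoidance
    experiments with head-mounted tracking markers and calcium-imaging
    fiber photometry. Decomposes two-marker head tracking into rotational
    and translational speed components, scales the 405 nm isosbestic
    channel to compute z-scored dF/F, detects movement peaks and head
    turns with direction labels, simulates the four shuttle-box avoidance
    procedures (AA1-AA4) with pluggable agent policies, extracts
    event-triggered snippets and windowed area/peak measures,
    cross-correlates movement with neural activity including
    200-ms-integrated linear fits and circular-shift shuffle controls,
    classifies neurons and trials with canonically ordered k-means, and
    fits windowed linear mixed-effects models with standardized covariates
    and marginal-means contrasts. A synthetic-data generator with stored
    ground truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
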