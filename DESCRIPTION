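Package: shoalmotion
Title: Collective-Motion Metrics and Reaction-Norm Models for Animal Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse collective motion in small animal groups tracked
    on video: reading per-frame trajectory data, quality filtering and
    Savitzky-Golay smoothing, six per-interval collective-motion statistics
    (polarization, centroid speed, convex hull area, polarized-state transition
    rate, maximum speed cross-correlation to the nearest neighbour, and
    leadership switch rate), and a behavioural reaction-norm statistical layer:
    linear mixed models with group random intercepts and random slopes over
    time, conditional AIC and AICc model selection with overfitting flags,
    between-group variance trends with parametric-bootstrap confidence
    intervals, a beta-family mixed model fitted by adaptive Gauss-Hermite
    quadrature, and an agent-based zonal schooling simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
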