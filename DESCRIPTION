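Package: dermabs
Title: Dose-Driven Estimation of Dermal Absorption from Multi-Concentration Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in vitro and in vivo dermal absorption
    studies on the absolute-dose scale. Fits linear models of
    log10(absorbed dose) against log10(applied dose), classifies fitted
    slopes against competing regulatory hypotheses (slope 0, between 0
    and 1, 1, above 1) using confidence intervals, and derives a single
    average relative dermal absorption value (DA_ave) as the
    back-transformed intercept under an assumed slope of 1 - algebraically
    the geometric mean of the per-dose-group relative absorption values.
    Includes the concentration-based comparator models used in European
    pesticide risk assessment (pro-rata extrapolation, relative absorption
    against concentration), mixed-effects variants with product-level
    random intercepts and marginal/conditional R-squared, a penetration
    probability toy model, a synthetic study generator for method
    validation, isoslope diagnostic plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    lme4,
    ggplot2,
    jsonlite,
    optparse,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
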