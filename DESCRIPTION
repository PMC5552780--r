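Package: ringN15
Title: Tree-Ring Nitrogen Isotope Chronologies and Trend Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing forest nitrogen availability from
    stable nitrogen isotope ratios measured in tree-ring wood. Implements
    per-core anomaly standardization against a modern reference window,
    two-stage decadal compositing across cores and sites, locally weighted
    regression smoothing with pointwise confidence bands, post-1970 trend
    estimation by core and site, multiple regression of site trends on
    climate and nitrogen-deposition covariates with Bonferroni outlier
    screening, basal-area-increment growth summaries, a tree-level mixed
    model with a site random intercept, and projection of fitted trends
    onto gridded climate surfaces with forest-area accounting. A synthetic
    data generator emulates the sampling structure of multi-site increment
    core collections so the full pipeline can be exercised with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lme4,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
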