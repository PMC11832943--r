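Package: dendrodecline
Title: Growth-Decline Analysis of Tree-Ring Series with Crown-Damage Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dendroecological analysis of declining tree stands:
    Tucson (.rwl) and long-CSV ring-width input, basal area increment (BAI)
    reconstruction from diameter at breast height, Hegyi competition index,
    cross-dating validation statistics, spline and mean-line standardization,
    Tukey biweight chronologies with EPS and Rbar signal-strength statistics,
    PCA-based classification of divergent growth trajectories, Mann-Kendall
    trend tests with trait regressions and crown-damage thresholds, station
    climate z-score departures with a precipitation-minus-temperature moisture
    index, bootstrapped monthly climate-growth correlations over the
    19-month southern-hemisphere season window, generalized additive models of
    climate sensitivity versus crown damage, and a synthetic stand and climate
    generator with ground truth for end-to-end parameter-recovery checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
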