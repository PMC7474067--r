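Package: normdev
Title: Normative Age Modelling of Regional Cortical Morphometry
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Growth-chart style normative modelling of regional cortical
    thickness (or any regional morphometric) against age. Fits per-region
    LOESS age trajectories on a typically-developing reference group with
    span selection by Brent optimization, tabulates one-year age-bin norms,
    converts case values to age-normed deviation scores (w-scores), flags
    region-wise statistical outliers, summarizes outlier prevalence and
    per-subject global deviation ratios, and contrasts normative inference
    with conventional site-random-effect mixed-model case-control testing.
    Includes a seeded synthetic-cohort generator, centile cross-checks,
    bootstrap reliability of deviation scores, power calculations, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
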