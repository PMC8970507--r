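Package: metiercost
Title: Disaggregation of Fishery Variable Costs from Fleet Segment to Metier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase methodology for disaggregating annual fishery variable
    costs (fuel cost, fuel consumption, labour cost) from fleet-segment
    resolution to metier resolution. Phase 1 assigns a prevalent metier to each
    vessel-year from trip-level activity, adjusts costs proportionally to the
    activity share, fits zero-intercept exploratory regressions and Gaussian
    GLMs with a metier factor, and selects a disaggregation equation through a
    decision flow. Phase 2 applies the fitted coefficients to official
    segment-level cost totals via metier-level transversal data (effort,
    landings value) and reconciles the result against the official totals.
    Includes a synthetic fleet generator with known ground-truth coefficients
    so the full pipeline can be exercised without confidential vessel data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
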