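Package: lakeanom
Title: Site-Specific Median Anomaly Trend Analysis for Lake Water Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting long-term trends in lake and reservoir
    water quality from irregular, multi-site monitoring records.
    Implements a site-specific median anomaly pipeline: eligibility
    filtering of monitoring sites, per-site annual medians, long-term
    reference medians, yearly cross-site median anomalies, ordinary
    least squares trend fitting, and a three-criterion ecological trend
    classification (statistical support, temporal pattern, and slope
    magnitude against ecologically derived thresholds). Includes a
    synthetic monitoring-program generator with staggered site
    enrollment, seasonal sampling schedules, skewed noise, injected
    trends, and detection-limit censoring, plus a Monte Carlo harness
    for comparing trend estimators against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
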