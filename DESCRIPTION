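Package: timescatter
Title: Animated Interval-Summary Scatter Layouts for Gene-Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory analysis of gene-expression time-course data via
    interval-summary scatter layouts: each gene is reduced, over a selected
    time window, to its mean activity (y) and change in activity (x), so that
    sweeping the window animates the plot and reveals patterns confined to
    sub-intervals that whole-profile clustering misses. Includes import of
    GDS SOFT and a native CSV dialect with replicate collapsing, per-value and
    reference rescaling with transform provenance, linear interpolation of
    missing values with interpolation-aware markers, zero-duration interval
    layout with endpoint snapping, axis-aligned box queries combined with
    Boolean AND/OR/NOT logic into shareable pattern files, gene-grouping
    import and smoothed convex outline overlays, headless rendering of
    scatter and line-chart frames, and a deterministic synthetic time-series
    generator with planted temporal patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    png,
    optparse
Config/testthat/edition: 3
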