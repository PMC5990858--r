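Package: diurnalseek
Title: Diurnal Rhythm Detection in Hourly Search-Volume Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies 24-hour (diurnal) patterns in hourly
    relative-search-volume (RSV) time series such as Google Trends hourly
    exports. Provides reading, validation and stitching of weekly RSV
    downloads, a Morlet continuous wavelet transform with band-limited
    inverse reconstruction (default 4-32 hour period band) to strip
    multi-day trends and sub-4-hour noise, folded 24-hour mean profiles
    with peak-trough differences in percentage points, an hourly
    directional significance matrix (one-way ANOVA with Tukey-Kramer
    pairwise comparisons), a trichotomized time-block analysis (ANOVA
    with Bonferroni-corrected post-hoc t tests), and a synthetic-data
    generator with known diurnal, trend and noise structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
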