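Package: leadtimesim
Title: Lead-Time Bias of Cancer Screening on Loss in Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microsimulation study of the lead-time bias that early detection
    through mammography screening induces in relative-survival based prognosis
    metrics: 10-year relative survival, loss in life expectancy (LLE) and
    proportion of life lost (PLL). Provides a breast-cancer natural-history
    generator (age-specific tumour onset, exponential tumour growth,
    size-driven symptomatic detection), life-table based other-cause mortality
    via the inversion method, cancer death times drawn from a relative-survival
    flexible parametric model, imposition of biennial screening programmes with
    size-dependent logistic sensitivity and imperfect attendance, maximum
    likelihood estimation of relative-survival flexible parametric models
    (restricted cubic splines of log time with time-dependent age effects),
    externally age-standardised (ICSS) predictions of 10-year relative
    survival, LLE and PLL with life-table extrapolation, and Monte Carlo
    summaries of absolute and relative bias over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    withr,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
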