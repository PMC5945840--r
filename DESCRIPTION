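Package: dfareg
Title: Scale-Dependent Bivariate Regression via Detrended Fluctuation
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale bivariate linear regression for nonstationary time
    series. Regression coefficients, their variances and evaluation indices
    (scale-dependent determination, beta and elasticity coefficients) are
    estimated at each time scale from detrended fluctuation analysis (DFA)
    variance and detrended cross-correlation analysis (DCCA) covariance
    functions. Includes DCCA and partial DCCA correlation coefficients,
    surrogate-shuffle Monte Carlo significance tests with per-scale critical
    values, simulators used for validation (ARFIMA fractional noise, binomial
    multifractal cascades, a synthetic multi-site PM2.5-like fixture), and
    CSV input/output with seasonal splitting for hourly exposure records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, tools, utils
Suggests: jsonlite, optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
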