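Package: stabilometry
Title: Centre-of-Pressure Sway Variables and Test-Retest Reliability for
    Modified Sensory Interaction Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the twelve stabilometric variables used to characterise
    60-second centre-of-pressure (CoP) recordings from a force platform:
    positional variability, path lengths and mean velocity in the time
    domain, sway area by a Fourier-series outline of extreme radii and by a
    95 percent PCA confidence ellipse, and Higuchi fractal dimensions of the
    medio-lateral and antero-posterior series over short and long lag
    regimes. Assesses test-retest reliability across the four modified
    Sensory Interaction Test conditions (firm or compliant surface, eyes
    open or closed) via ICC(2,1) with Shrout-Fleiss confidence intervals,
    standard errors of measurement and Romberg quotients, and provides a
    synthetic-cohort generator with a known variance-components structure so
    the whole pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
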