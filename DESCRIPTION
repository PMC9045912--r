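Package: jmoct
Title: Jones-Matrix and Spectral-Domain OCT Contrast Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for polarization-sensitive
    Jones-matrix optical coherence tomography (JM-OCT) and intensity-based
    spectral-domain OCT (SD-OCT). Generates layered speckle phantoms with
    known ground truth (attenuation, birefringence, polarization
    scrambling); computes the four JM-OCT tissue contrasts - scatter
    intensity, depth-resolved attenuation coefficient, local birefringence
    with a maximum a posteriori estimator and reliability map, and degree
    of polarization uniformity (DOPU); reconstructs SD-OCT B-scans from raw
    spectral fringes (k-linearization, spectral shaping, dispersion
    compensation, fixed-pattern removal); stitches laterally overlapping
    volume tiles by phase correlation; and quantifies region-of-interest
    differences (e.g. tumor versus control tissue) with per-B-scan means,
    box-whisker summaries, Mann-Whitney U and Levene tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
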