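Package: magtrack
Title: Differential Static Magnetic Localisation and Tracking of Capsule Endoscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for tracking permanent-magnet-bearing
    capsule endoscopes with an external magnetometer array. Implements the magnetic
    dipole field of a cylindrical magnet (with a finite-volume validation oracle),
    a 12-sensor elliptical-ring array with a realistic measurement chain (noise,
    clipping, quantisation, averaging), hard-/soft-iron ellipsoid calibration,
    differential pair-residual pose estimation by Levenberg-Marquardt that cancels
    the homogeneous geomagnetic background exactly, gastrointestinal-tract-scale
    synthetic trajectories, and the traveled-distance and orientation-error
    evaluation protocol with 30-run batch statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
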