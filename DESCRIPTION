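Package: recurtrap
Title: Transient Trapping Detection in Single-Particle Trajectories via
    Recurrence Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transient trapping (confinement) events inside
    individual 2D/3D single-particle-tracking trajectories by quantifying
    block structures along the diagonal of a smoothed, thresholded Gaussian
    recurrence matrix. Provides the full pipeline (trajectory
    standardization, recurrence matrix, box smoothing, thresholding,
    lacunarity filling, diagonal banding, diagonal run-length measures and
    their block invariant), Monte-Carlo calibration of the diagonal band
    count and of the minimal statistically significant block size,
    single- and multi-lengthscale detection with p-value filtering,
    trajectory simulators (Brownian, exact fractional Brownian via
    Davies-Harte, reflected confined motion, alternating two-state motion
    with ground truth and localisation noise), and post-analysis statistics
    (trap geometry, time-averaged MSD fitting of anomalous diffusion,
    per-group trapped fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
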