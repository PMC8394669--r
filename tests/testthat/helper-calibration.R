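# Scaled-down Brownian-reference calibration shared by the statistical
# tests: 2D, mu = 2; null stage at 200 trajectories x 2000 steps, band-count
# stage at 100 trajectories (the band count is already stable there).
# Built lazily once per test run (it takes a few minutes).
acceptance_calibration <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- build_calibration(
        models = "bm", dims = 2, lambdas = c(1, 3), mu = 2,
        p_values = 0.05,
        n_traj_band = 100, n_steps_band = 2000,
        n_traj_null = 200, n_steps_null = 2000,
        seed = 424243)
    }
    tab
  }
})
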