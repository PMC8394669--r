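# recurtrap

Detection of transient trapping events inside individual 2D/3D
single-particle-tracking trajectories, for cell biologists and biophysicists
analysing the motion of membrane receptors and intracellular particles.

Freely diffusing molecules on the plasma membrane are transiently caught in
nanoscopic domains. Treating such an intermittent trajectory as one
homogeneous motion (e.g. fitting a single anomalous exponent) misreads the
biology. `recurtrap` segments a *single* trajectory into free and trapped
portions — no sliding window, no need for several molecules to visit the
same domain.

## Method in brief

For a standardized trajectory \{x_1, …, x_N\} and a test lengthscale λ, the
Gaussian-weight recurrence matrix

    M_ij = exp( -(|x_i - x_j| / λ)² / 2 )

is smoothed by a (2μ+1)² moving average, thresholded at p_c = e⁻¹ into a
binary matrix B, hole-filled, and augmented with n_d diagonal bands. A
trapped stretch appears as a square block of 1s on the diagonal of B. For
every diagonal index n, three run lengths — block time t|(n) (vertical),
neighbouring time t⊥(n) (anti-diagonal) and persistence time t‖(n)
(diagonal-parallel through the anti-diagonal run's extremity) — combine
into the block invariant

    ν(n) = t|(n) / ( t‖(n) + t⊥(n) - 1 ),

which equals 1 at every point of an ideal block and collapses toward 0 on
free stretches. Frames with ν(n) > ν_c (= 3/4) form candidate blocks; a
block is accepted only if its size is statistically incompatible (at
p = 0.05) with the Monte-Carlo null distribution of block sizes produced by
reference free motion (Brownian, or subdiffusive fractional Brownian with
H = 0.35). Both the band count n_d and the minimal significant block size
τ_p are calibrated by simulation per (reference model, dimension, λ, μ).
Unknown trap sizes are handled by running several lengthscales and taking
the union of trapped frames.

Post-analysis utilities quantify each detected trap (centre = coordinate-wise
median, radius = nearest-rank 95th-percentile distance), the trapped
fraction per group of trajectories, and the free-portion dynamics by fitting
the time-averaged MSD, δ²(n) = 4 D_α n^α + 4 σ_err², over lags 1–5.

## Worked example

```r
library(recurtrap)

# 1. Calibrate the detector against 2D Brownian reference motion at λ = 1
#    (a couple of minutes; persist with write_calibration() and reuse)
tab <- build_calibration(models = "bm", dims = 2, lambdas = 1, mu = 2,
                         n_traj_band = 100, n_steps_band = 2000,
                         n_traj_null = 200, n_steps_null = 2000, seed = 7)
print(tab)
#> <calibration_table: 1 entries>
#>   bm 2D lambda=1 mu=2: n_d=3, 22732 null blocks, tau=0.05:8

# 2. Simulate a ground-truth trajectory: Brownian flights (mean 20 frames)
#    alternating with traps of radius 1 (mean 60 frames), 10% noise
lt <- simulate_alternating(1000, dim = 2, tau_free = 20, tau_trap = 60,
                           radius = 1, noise_sigma = 0.1, seed = 11)

# 3. Detect trapping at λ = 1 and score against the truth
seg <- detect_single_scale(lt$trajectory, lambda = 1, tab, reference = "bm")
print(seg)
#> <segmentation 'alternating': 1000 frames, 703 trapped (70.3%), 13 block(s)>
recognition_score(seg, lt)
#> [1] 0.954
```

The calibration table says: after thresholding, free Brownian motion at
λ = 1 needs n_d = 3 diagonal bands, and any candidate block shorter than
τ_0.05 = 8 frames is rejected as a chance block of free motion. The
segmentation recovers the trapped portions with 95.4% frame-level agreement
with the ground truth.

A thin command-line front end over the same functions lives at
`inst/cli/trapdetect.R` (subcommands `simulate`, `calibrate`, `detect`,
`benchmark`, `analyze`), for shell pipelines working with trajectory CSV
files (`traj_id,frame,x,y[,z]`).

The methods vignette (`vignettes/trapping-detection.Rmd`) documents the
model, the calibration, the simulators and all numerical choices.

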