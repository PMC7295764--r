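# spheroquant

Quantification pipeline for interstitial-flow-driven tumor-spheroid
dissociation assays: time-lapse fluorescence movies of co-culture spheroids
(e.g. MDA-MB-231 + MCF-10A in collagen), and the statistics that describe
what the flow does to them. For image-analysis users who need the published
readouts as tested, reusable R functions — and, since such assays rarely ship
raw data, a synthetic phantom generator whose ground truth validates every
estimator.

## What it computes

* **Spheroid size** — azimuthally averaged radial intensity profile about
  the frame-0 centroid, fitted per frame to
  `density(r) = A·exp(−r²/(2σ²)) + B`; the fitted `σ` is the spheroid size
  and `σ(t)/σ(0)` the normalized size. Plus counts of dissociated single
  cells beyond `3σ₀`.
* **Motility** — per-cell migration speed (path length / time), ensemble
  mean squared displacement `MSD(τ)` (time-averaged then pooled with
  pair-count weights), diffusion coefficient from the 2D model
  `MSD = 4Dτ` (weighted fit through the origin), and flow-axis statistics
  `Vx` (net velocity) and `Px` (forward-migration index) with a one-sample
  t-test for directional bias. A minimal LoG detector + gated
  nearest-neighbour linker turns sparse movies into tracks.
* **Morphology** — Otsu segmentation, moment-equivalent ellipse per cell
  (ImageJ "Fit Ellipse" convention), aspect ratio `AR = major/minor`,
  mesenchymal (`AR ≥ 2`, inclusive) vs amoeboid classification, population
  fraction ± binomial SE.
* **Marker intensity** — sum z-projection of confocal stacks, histogram-mode
  background subtraction, total intensity per spheroid, unit-area intensity
  distributions, and two-group Student's t comparisons (mean ± SEM).
* **Phantoms** — dissociating Gaussian-cloud spheroid movies, Brownian /
  fixed-step / persistent-random-walk trajectories, non-overlapping ellipse
  fields with calibrated AR mixtures, and marker z-stacks; all with sidecar
  ground truth and seed-reproducible output.

## Worked example

```r
library(spheroquant)

spec <- phantom_spec(
  image_shape = c(512L, 512L), pixel_size = 1.3, frame_interval = 20,
  n_frames = 12L, rng_seed = 1L,
  channels = list(green = spheroid_phantom_spec(n_cells = 300, sigma0 = 30,
                                                fold_final = 3.8)))
ph <- generate_spheroid_timelapse(spec)
ss <- size_series(ph$series, "green")
tail(ss, 1)
#>    frame time_min    sigma normalized_size converged
#> 12    11      220 111.2418        3.741282      TRUE

tr <- generate_trajectories(trajectory_phantom_spec(
  121L, "brownian", D = 6.41, duration = 17 * 60, rng_seed = 1L))
fit_diffusion_coefficient(compute_msd(tr$ts))
#> <diffusion_fit> D = 6.45 +/- 0.02 um^2/min (12 lags)
```

The movie's cell cloud was scheduled to grow 3.8-fold over the acquisition;
the radial-profile + Gaussian-fit chain reads back 3.74. The trajectory
phantom diffuses with D = 6.41 µm²/min; the MSD + 4Dτ fit recovers 6.45
(within sampling error for 121 cells).

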