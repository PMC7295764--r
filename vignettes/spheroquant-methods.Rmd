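---
title: "Quantifying interstitial-flow-driven spheroid dissociation: methods and design notes"
author: "spheroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interstitial-flow-driven spheroid dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroquant)
```

## The measurement problem

A co-culture breast tumor spheroid (metastatic MDA-MB-231 cells plus
non-tumorigenic MCF-10A cells) embedded in a collagen matrix loses its
compact core when slow interstitial flow (~2 um/s) passes through the
matrix: cells detach, invade, change shape and speed, and lose E-cadherin.
Each of those observations rests on a specific quantification of time-lapse
or confocal fluorescence images:

* **spheroid size** — the scale `sigma` of a Gaussian fitted to the
  azimuthally averaged radial intensity profile of one fluorescence channel,
  normalised to its value at `t = 0`;
* **motility** — per-cell speed, ensemble mean squared displacement (MSD),
  and the 2D diffusion coefficient `D` from `MSD = 4 D tau`;
* **morphology** — the aspect ratio (AR) of the moment-equivalent ellipse of
  each segmented cell, with `AR >= 2` labelled mesenchymal (elongated) and
  `AR < 2` amoeboid (rounded);
* **marker intensity** — the background-subtracted total of a sum
  z-projection of a confocal stack, plus the normalised distribution of
  positive pixel intensities.

spheroquant implements these four estimator chains and, because the original
microscopy data are not publicly deposited, a phantom generator that renders
synthetic inputs with every ground-truth parameter recorded in a sidecar.
All validation compares pipeline estimates against sidecar truth, never
against another image-derived estimate.

## What the phantoms emulate

Acquisition constants follow the experimental protocol: frames every
**20 minutes**, **109 frames** (36 h), a 10X field stored as 16-bit counts.
The pixel scale defaults to **0.65 um/pixel**, a typical 10X CCD scale;
magnification alone does not determine it, so it is configurable and every
physical result is expressed in micrometres and minutes.

**Dissociating spheroid.** Each population is a 2D isotropic Gaussian cloud
of `n_cells` Gaussian spots. Per-cell offsets are drawn once and scaled by
`sigma(t)`, which ramps linearly from `sigma0` to `fold_final * sigma0`; the
functional form of dissociation over time is not constrained by any reported
measurement, and the recovery checks depend only on the endpoint fold, so
the simplest monotone schedule is used. Scaling a frozen cloud (rather than
re-drawing positions each frame) makes cells move smoothly outward, keeps
every frame an exact draw from the scheduled Gaussian, and removes
position-resampling noise from the normalised size ratio. A configurable
`detach_fraction` of cells is instead seeded uniformly in the annulus from
`3 * sigma0` to the field edge, so detached singles are unambiguous for
counting tests.

**Trajectories.** Three motility models at 20-min sampling: Brownian
(i.i.d. Gaussian steps, per-axis variance `2 D dt`), fixed-step (exact step
length, uniform heading — the speed ground truth is then exact by
construction), and a persistent random walk whose velocity is an
Ornstein-Uhlenbeck process integrated at 20 substeps per frame, giving the
Fuerth MSD `4 D (tau - P (1 - exp(-tau/P)))` with `D = v^2 P / 2`. The
reported speed/D pairs for real cells imply persistent, not Brownian, motion
— a single phantom cannot match both a printed speed and a printed `D` with
a Brownian walker — so speed recovery uses fixed-step phantoms and diffusion
recovery uses Brownian phantoms, each calibrated to its own statistic; the
PRW mode provides joint realism for property tests.

**Shapes.** Non-overlapping filled ellipses with prescribed ARs (explicit
list or a two-component lognormal mixture; `ar_mixture_for_fraction()`
solves the mixture weight so the expected fraction with `AR >= 2` hits a
target). Placement is random sequential adsorption with bounded retries.

**Marker z-stacks.** 5-6 slices (13.36 um thick) of constant background
plus per-cell Gaussian spots whose xy and z weights are normalised exactly,
so before noise and quantisation the signal above background equals
`n_positive_cells * per_cell_intensity`. With the default integer
quantisation (the camera model) sub-count spot tails floor to zero, so
quantified totals land a few percent *below* truth for faint cells; the
exact-conservation property is tested with `quantize = FALSE`.

All generators derive every random draw from one seed; identical seed and
spec give bit-identical output.

What the phantoms deliberately omit: optical point-spread blur,
photobleaching, stage drift, intensity flicker, collagen autofluorescence
texture, and any mechanical interaction between cells. Passing recovery
tests therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to every artefact of real microscopy.

## Estimator design choices

**Centre definition.** The spheroid centre is the intensity-weighted
centroid of the background-subtracted, channel-summed frame 0, held fixed
afterwards. A fixed centre anchors the radial coordinate to the initial
spheroid and avoids feedback between dissociation and the coordinate system.

**Radial profile.** Pixels are assigned to annuli `[r, r + bin_width)`
(default two pixels wide) by the distance of their centre; the density is
the mean intensity per annulus. Empty annuli are reported `NA` and flagged,
never interpolated.

**Gaussian size fit.** `density(r) = A exp(-r^2 / (2 sigma^2)) + B` by
Levenberg-Marquardt least squares, annuli weighted by their pixel count
(the variance of an azimuthal mean is inversely proportional to the number
of pixels averaged; unweighted fits let the noisy few-pixel innermost bins
drag `sigma`). The baseline `B` absorbs camera offset. Initialisation:
`A` from the density range, `B` from the outer-20% median, and `sigma` from
the radial second moment of the baseline-subtracted profile — a half-maximum
crossing is cheaper but occasionally latches onto a single noisy bin and
collapses the fit to a spike. Convergence tolerance 1e-8, at most 1000
function evaluations; non-converged frames are reported `NA` and dropped
from downstream statistics rather than imputed, except frame 0, whose
failure is a hard error because it anchors the normalisation. Note that for
a 2D Gaussian cloud the disc of radius `sigma` contains
`1 - exp(-1/2) ~ 39%` of the cells; `sigma` is used strictly as the fitted
scale parameter, with no enclosed-mass interpretation attached.

**Dissociated singles.** Otsu's threshold computed on log-compressed
background-subtracted intensities — on a linear scale the spheroid core is
so much brighter than one cell that Otsu separates dim cells from the core
instead of signal from background. Components count as dissociated singles
when their centroid is beyond `k * sigma0` (default `k = 3`) and their area
lies within bounds derived from the nominal cell radius (default 0.5-15
times the spot area `pi r^2`). Touching singles merge into one oversize
component and are undercounted; this is a documented failure mode, not
corrected.

**Tracking.** The original analysis used an unspecified in-house tracker, so
the package ships the minimal defensible stand-in: Laplacian-of-Gaussian
spot detection (negative-LoG response, 8-neighbour local maxima above a
response quantile, 5x5 centroid refinement for subpixel position) and greedy
frame-to-frame linking by ascending distance — each accepted pair is a
mutual nearest neighbour among remaining candidates — with a displacement
gate defaulting to 4x the expected step. No gap closing, because no basis
for a gap model is reported. An undersized gate fragments tracks instead of
mislinking them.

**Speed.** Path length divided by tracked time, `sum|dr| / (n_steps dt)`;
cells seen in fewer than two frames are excluded and counted.

**MSD and D.** Time-averaged squared displacements over all start times
within each cell (tracks are aligned by track-relative time, since cells
enter tracking at different absolute times), pooled across cells with
per-lag pair-count weights. Lags are reported up to a quarter of the longest
track duration, where time averages remain statistically reliable. `D` comes
from weighted least squares of `msd = 4 D tau` through the origin — the
first-order 2D diffusion model has no intercept, though an intercept option
exists — with the closed form `D = sum(w tau msd) / (4 sum(w tau^2))`. The
2D formula is used because tracking is 2D even though cells move in a 3D
matrix.

**Directional statistics.** `Vx = net x-displacement / duration` and
`Px = net x-displacement / path length` (a forward-migration index in
[-1, 1]; `Px` is a convention adopted here, as no formal definition is
reported), with a one-sample Student's t-test of per-cell `Vx` against zero.

**Morphology.** Background subtraction, Otsu threshold, connected
components, area filter (touching cells merge and are excluded as oversize
rather than split); per mask, the ellipse with the same area and second
central moments as the pixel set — the ImageJ "Fit Ellipse" convention —
gives `AR = sqrt(l1 / l2)` from the covariance eigenvalues. The mesenchymal
threshold is inclusive at exactly `AR = 2.0`. Segmentation operates on
thresholded masks; whether the original cells were outlined manually is not
recorded, and this choice is validated end-to-end against sidecar ARs
(Kolmogorov-Smirnov agreement on noiseless phantoms).

**Marker quantification.** Sum projection (exact pixelwise slice addition),
background from the histogram mode of the projection (background pixels
dominate a spheroid field; a dark-percentile median is available for
crowded fields), clip at zero, sum. The normalised distribution pools
positive background-subtracted pixels per condition into a unit-area
256-bin histogram. Consecutive confocal slices overlap by 4.4 um in the
emulated protocol, so totals are slightly overestimated on real stacks;
phantoms reproduce this by slice duplication and the bias is deliberately
left uncorrected to mirror the published procedure.

**Group statistics.** Equal-variance two-sided Student's t-test (Welch
available behind a flag), mean +/- SEM throughout, SEM undefined at n = 1
and reported missing, no multiple-testing correction (none was applied in
the original analysis). Zero-variance identical groups return t = 0, p = 1
by convention.

## Validation scales

The test suite regenerates every fixture from code at run time. Recovery
checks run at the study's cohort sizes where they are cheap (121-169 tracks
over 17 h; 46-107 tracks over 10 h; 150-cell shape phantoms) and at reduced
rendering sizes where they are not: spheroid movies for multi-seed endpoint
checks use 12-frame schedules on a 512x512 field at 1.3 um/pixel with 300
cells per population (the endpoint-fold estimate depends only on the
schedule endpoint), while single full 109-frame movies verify the 36-h
comparison. Stochastic recovery checks compare ensemble means over fixed
seed schedules — 10 replicate phantoms for diffusion coefficients and
endpoint folds, sized so three standard errors of the mean sit below the
check tolerance — and sampling-error bounds (3 SE, binomial or chi-square)
everywhere a single draw is asserted.

## Worked example

```{r example, eval = FALSE}
# a dissociating two-channel spheroid movie with known schedule
spec <- phantom_spec(
  image_shape = c(512L, 512L), pixel_size = 1.3, frame_interval = 20,
  n_frames = 12L, rng_seed = 1L,
  channels = list(green = spheroid_phantom_spec(n_cells = 300, sigma0 = 30,
                                                fold_final = 3.8)))
ph <- generate_spheroid_timelapse(spec)
ss <- size_series(ph$series, "green")
tail(ss, 1)          # recovered endpoint fold vs the scheduled 3.8

# motility statistics on a Brownian phantom
tr <- generate_trajectories(trajectory_phantom_spec(
  121L, "brownian", D = 6.41, duration = 17 * 60, rng_seed = 1L))
fit_diffusion_coefficient(compute_msd(tr$ts))
```

## Known limitations

* Estimator accuracy on real data is bounded by effects the phantoms omit
  (PSF blur, drift, uneven illumination); the package validates algorithmic
  correctness, not acquisition robustness.
* The size fit assumes an approximately Gaussian radial profile; strongly
  ring-shaped or lobed dissociation patterns would need a different model.
* The linker has no gap closing and no motion model; dense fields or long
  detection dropouts fragment tracks (by design, visibly, rather than
  silently mislinking).
* Quantised 16-bit rendering floors sub-count intensities, so faint-cell
  marker totals are a few percent low relative to sidecar truth; use
  `quantize = FALSE` when exact conservation matters.
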