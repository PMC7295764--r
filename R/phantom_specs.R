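#' Acquisition-level phantom specification
#'
#' Holds the acquisition constants shared by all synthetic inputs: field size,
#' physical pixel scale, frame interval and number of frames, the RNG seed, and
#' the list of population specs to render (one per fluorescence channel). The
#' defaults mirror a typical 10X CCD time-lapse acquisition: 20-minute frame
#' interval, 109 frames (36 h), 0.65 um/pixel.
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param pixel_size physical pixel scale, um/pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames.
#' @param rng_seed integer seed; identical seed + spec give bit-identical
#'   output.
#' @param channels named list of population specs (see
#'   [spheroid_phantom_spec()]).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(512L, 512L), pixel_size = 0.65,
                         frame_interval = 20, n_frames = 109L,
                         rng_seed = 1L, channels = list()) {
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE, integer = TRUE)
  stopifnot_scalar(rng_seed, "rng_seed", integer = TRUE)
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop("image_shape must be c(rows, cols) with both >= 8")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), rng_seed = as.integer(rng_seed),
                 channels = channels),
            class = "phantom_spec")
}

#' Dissociating-spheroid population spec
#'
#' Describes one fluorescent cell population rendered as a 2D Gaussian cell
#' cloud whose scale sigma(t) grows linearly from `sigma0` at frame 0 to
#' `fold_final * sigma0` at the last frame. A fraction of cells can be
#' re-seeded outside the core (uniformly in the annulus from `3 * sigma0` to
#' the field edge) as dissociated singles for counting tests.
#'
#' @param n_cells cells in the population.
#' @param sigma0 initial cloud scale, um.
#' @param fold_final sigma at the last frame divided by sigma0 (>= 1).
#' @param cell_radius rendered Gaussian spot scale, um.
#' @param detach_fraction fraction of cells re-seeded as isolated singles.
#' @param noise_sd additive Gaussian camera noise, intensity counts.
#' @param cell_intensity integrated counts per rendered cell.
#' @return object of class `spheroid_phantom_spec`.
#' @export
spheroid_phantom_spec <- function(n_cells = 300L, sigma0 = 30, fold_final = 1,
                                  cell_radius = 4, detach_fraction = 0,
                                  noise_sd = 2, cell_intensity = 2000) {
  stopifnot_scalar(n_cells, "n_cells", positive = TRUE, integer = TRUE)
  stopifnot_scalar(sigma0, "sigma0", positive = TRUE)
  stopifnot_scalar(fold_final, "fold_final")
  if (fold_final < 1) stop("fold_final must be >= 1")
  if (detach_fraction < 0 || detach_fraction > 1)
    stop("detach_fraction must be in [0, 1]")
  stopifnot_scalar(cell_radius, "cell_radius", positive = TRUE)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_cells = as.integer(n_cells), sigma0 = sigma0,
                 fold_final = fold_final, cell_radius = cell_radius,
                 detach_fraction = detach_fraction, noise_sd = noise_sd,
                 cell_intensity = cell_intensity),
            class = "spheroid_phantom_spec")
}

#' Random-walk trajectory phantom spec
#'
#' Three motility modes are supported. `brownian` draws i.i.d. Gaussian steps
#' with per-axis variance `2 * D * dt`. `fixed_step` takes steps of exactly
#' `step_length` um per frame in a uniformly random direction, so the
#' ground-truth speed is `step_length / frame_interval` by construction.
#' `prw` is a persistent random walk whose velocity follows an
#' Ornstein-Uhlenbeck process with persistence time `P` and RMS speed `v`,
#' giving the Fuerth ensemble MSD `4 D (tau - P (1 - exp(-tau / P)))` with
#' `D = v^2 P / 2`.
#'
#' @param n_cells number of trajectories.
#' @param mode `"brownian"`, `"fixed_step"` or `"prw"`.
#' @param D diffusion coefficient, um^2/min (brownian only).
#' @param step_length um per frame (fixed_step only).
#' @param v RMS speed, um/min (prw only).
#' @param P persistence time, minutes (prw only).
#' @param duration total tracked time, minutes.
#' @param frame_interval minutes between samples.
#' @param rng_seed integer seed.
#' @return object of class `trajectory_phantom_spec`.
#' @export
trajectory_phantom_spec <- function(n_cells, mode = c("brownian", "fixed_step", "prw"),
                                    D = NULL, step_length = NULL, v = NULL, P = NULL,
                                    duration = 1020, frame_interval = 20,
                                    rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot_scalar(n_cells, "n_cells", positive = TRUE, integer = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  need <- switch(mode,
                 brownian = list(D = D),
                 fixed_step = list(step_length = step_length),
                 prw = list(v = v, P = P))
  extra <- setdiff(c("D", "step_length", "v", "P")[
    !vapply(list(D, step_length, v, P), is.null, logical(1))], names(need))
  if (length(extra)) stop("parameters not used by mode '", mode, "': ",
                          paste(extra, collapse = ", "))
  for (nm in names(need)) {
    if (is.null(need[[nm]])) stop("mode '", mode, "' requires '", nm, "'")
    if (need[[nm]] < 0) stop("'", nm, "' must be >= 0")
  }
  structure(c(list(n_cells = as.integer(n_cells), mode = mode,
                   duration = duration, frame_interval = frame_interval,
                   rng_seed = as.integer(rng_seed)), need),
            class = "trajectory_phantom_spec")
}

#' Ellipse-shaped cell image phantom spec
#'
#' Cells are rendered as filled ellipses with prescribed aspect ratios, either
#' given explicitly (`ar_values`) or drawn from a two-component lognormal
#' mixture (`ar_mixture = list(meanlog, sdlog, weights)`), at uniformly random
#' orientations and non-overlapping uniformly random positions.
#'
#' @param n_cells number of cells.
#' @param ar_values explicit aspect ratios (recycled to `n_cells`), or NULL.
#' @param ar_mixture two-component lognormal mixture: list with numeric
#'   `meanlog` (length 2), `sdlog` (length 2), `weights` (length 2, sum 1).
#' @param cell_area area per cell, um^2.
#' @param image_shape c(rows, cols) pixels.
#' @param pixel_size um/pixel.
#' @param noise_sd additive Gaussian noise, counts.
#' @param cell_intensity foreground level, counts.
#' @param rng_seed integer seed.
#' @return object of class `shape_phantom_spec`.
#' @export
shape_phantom_spec <- function(n_cells = 150L, ar_values = NULL, ar_mixture = NULL,
                               cell_area = 200, image_shape = c(1536L, 1536L),
                               pixel_size = 0.65, noise_sd = 0,
                               cell_intensity = 1000, rng_seed = 1L) {
  stopifnot_scalar(n_cells, "n_cells", positive = TRUE, integer = TRUE)
  stopifnot_scalar(cell_area, "cell_area", positive = TRUE)
  if (is.null(ar_values) == is.null(ar_mixture))
    stop("exactly one of ar_values or ar_mixture must be given")
  if (!is.null(ar_values) && any(ar_values < 1))
    stop("aspect ratios must be >= 1")
  if (!is.null(ar_mixture)) {
    stopifnot(is.list(ar_mixture),
              all(c("meanlog", "sdlog", "weights") %in% names(ar_mixture)),
              length(ar_mixture$weights) == 2L,
              abs(sum(ar_mixture$weights) - 1) < 1e-9)
  }
  structure(list(n_cells = as.integer(n_cells), ar_values = ar_values,
                 ar_mixture = ar_mixture, cell_area = cell_area,
                 image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 noise_sd = noise_sd, cell_intensity = cell_intensity,
                 rng_seed = as.integer(rng_seed)),
            class = "shape_phantom_spec")
}

#' Confocal marker z-stack phantom spec
#'
#' Emulates a 5-6 slice confocal acquisition of membrane-marker fluorescence:
#' each positive cell contributes a fixed integrated intensity spread over a
#' Gaussian spot in xy and across neighbouring z slices, on top of a constant
#' per-slice background.
#'
#' @param n_slices slices in the stack (typically 5 or 6).
#' @param slice_thickness um per slice.
#' @param image_shape c(rows, cols) pixels.
#' @param pixel_size um/pixel.
#' @param n_positive_cells marker-positive cells.
#' @param per_cell_intensity integrated counts per positive cell.
#' @param background_level constant background per slice, counts.
#' @param noise_sd additive Gaussian noise per pixel, counts.
#' @param cell_radius xy spot scale, um.
#' @param rng_seed integer seed.
#' @return object of class `stack_phantom_spec`.
#' @export
stack_phantom_spec <- function(n_slices = 6L, slice_thickness = 13.36,
                               image_shape = c(256L, 256L), pixel_size = 1.66,
                               n_positive_cells = 50L, per_cell_intensity = 1000,
                               background_level = 5, noise_sd = 0,
                               cell_radius = 6, rng_seed = 1L) {
  stopifnot_scalar(n_slices, "n_slices", positive = TRUE, integer = TRUE)
  stopifnot_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  if (n_positive_cells < 0) stop("n_positive_cells must be >= 0")
  if (per_cell_intensity < 0 || background_level < 0 || noise_sd < 0)
    stop("intensities and noise_sd must be >= 0")
  structure(list(n_slices = as.integer(n_slices), slice_thickness = slice_thickness,
                 image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 n_positive_cells = as.integer(n_positive_cells),
                 per_cell_intensity = per_cell_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 cell_radius = cell_radius, rng_seed = as.integer(rng_seed)),
            class = "stack_phantom_spec")
}
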