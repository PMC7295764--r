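# Phantom generators: determinism, ground-truth closure, and the sampling
# properties each downstream estimator relies on.

small_spheroid_spec <- function(seed = 1L, n_frames = 3L, fold = 3,
                                detach = 0, noise = 0) {
  phantom_spec(image_shape = c(128L, 128L), pixel_size = 1.3,
               n_frames = n_frames, rng_seed = seed,
               channels = list(green = spheroid_phantom_spec(
                 n_cells = 60L, sigma0 = 12, fold_final = fold,
                 detach_fraction = detach, noise_sd = noise)))
}

test_that("identical seed and spec give bit-identical phantoms", {
  a <- generate_spheroid_timelapse(small_spheroid_spec(7L))
  b <- generate_spheroid_timelapse(small_spheroid_spec(7L))
  expect_identical(a$series$pixels, b$series$pixels)
  expect_identical(a$sidecar$positions, b$sidecar$positions)
  c <- generate_spheroid_timelapse(small_spheroid_spec(8L))
  expect_false(identical(a$series$pixels, c$series$pixels))

  t1 <- generate_trajectories(trajectory_phantom_spec(5L, "brownian", D = 1,
                                                      duration = 100, rng_seed = 3L))
  t2 <- generate_trajectories(trajectory_phantom_spec(5L, "brownian", D = 1,
                                                      duration = 100, rng_seed = 3L))
  expect_identical(t1$ts$x, t2$ts$x)

  s1 <- generate_shape_image(shape_phantom_spec(10L, ar_values = 2,
                                                image_shape = c(256L, 256L),
                                                rng_seed = 4L))
  s2 <- generate_shape_image(shape_phantom_spec(10L, ar_values = 2,
                                                image_shape = c(256L, 256L),
                                                rng_seed = 4L))
  expect_identical(s1$image, s2$image)

  z1 <- generate_marker_zstack(stack_phantom_spec(n_positive_cells = 5L, rng_seed = 2L))
  z2 <- generate_marker_zstack(stack_phantom_spec(n_positive_cells = 5L, rng_seed = 2L))
  expect_identical(z1$zstack, z2$zstack)
})

test_that("sigma schedule interpolates linearly to the endpoint fold", {
  spec <- phantom_spec(image_shape = c(2048L, 2048L), pixel_size = 1.3,
                       n_frames = 5L, rng_seed = 1L,
                       channels = list(g = spheroid_phantom_spec(
                         n_cells = 300L, sigma0 = 50, fold_final = 3)))
  ph <- generate_spheroid_timelapse(spec)
  sched <- ph$sidecar$sigma_schedule
  expect_equal(sched$sigma[1L], 50)
  expect_equal(sched$sigma[nrow(sched)], 150)
  expect_equal(diff(sched$sigma), rep(25, 4))
})

test_that("static spheroid phantom with frozen positions repeats frames exactly", {
  ph <- generate_spheroid_timelapse(small_spheroid_spec(5L, fold = 1, noise = 0))
  expect_identical(ph$series$pixels[, , 1L, 1L], ph$series$pixels[, , 3L, 1L])
})

test_that("cell radial positions have variance sigma(t)^2 (sidecar moment oracle)", {
  ratios <- vapply(1:20, function(seed) {
    ph <- generate_spheroid_timelapse(small_spheroid_spec(seed, n_frames = 3L))
    pos <- ph$sidecar$positions
    last <- pos[pos$frame == 2L & !pos$detached, ]
    sig <- ph$sidecar$sigma_schedule$sigma[3L]
    ctr <- ph$sidecar$center
    mean((last$x - ctr[1L])^2 + (last$y - ctr[2L])^2) / (2 * sig^2)
  }, numeric(1))
  # mean of r^2/(2 sigma^2) over n cells has SE 1/sqrt(n) per seed
  se <- 1 / sqrt(60 * 20)
  expect_lt(abs(mean(ratios) - 1), 3 * se)
})

test_that("detached singles are seeded outside 3 sigma0 and flagged", {
  ph <- generate_spheroid_timelapse(small_spheroid_spec(2L, detach = 0.2))
  pos <- ph$sidecar$positions
  det <- pos[pos$detached & pos$frame == 0L, ]
  expect_equal(nrow(det), 12L)
  ctr <- ph$sidecar$center
  d <- sqrt((det$x - ctr[1L])^2 + (det$y - ctr[2L])^2)
  expect_true(all(d >= 3 * 12))
})

test_that("cells rendered outside the field are flagged as clipped", {
  spec <- phantom_spec(image_shape = c(64L, 64L), pixel_size = 1,
                       n_frames = 1L, rng_seed = 1L,
                       channels = list(g = spheroid_phantom_spec(
                         n_cells = 200L, sigma0 = 60, fold_final = 1)))
  ph <- generate_spheroid_timelapse(spec)
  expect_gt(sum(ph$sidecar$positions$clipped), 0L)
})

test_that("fixed-step displacements are exact and brownian steps have variance 2 D dt", {
  fx <- generate_trajectories(trajectory_phantom_spec(10L, "fixed_step",
                                                      step_length = 4,
                                                      duration = 400,
                                                      frame_interval = 20,
                                                      rng_seed = 11L))
  for (d in split(fx$ts, fx$ts$cell_id)) {
    expect_equal(sqrt(diff(d$x)^2 + diff(d$y)^2), rep(4, nrow(d) - 1L),
                 tolerance = 1e-12)
  }
  expect_equal(fx$sidecar$speed, 0.2)

  br <- generate_trajectories(trajectory_phantom_spec(500L, "brownian", D = 1,
                                                      duration = 1000,
                                                      frame_interval = 20,
                                                      rng_seed = 12L))
  steps <- unlist(lapply(split(br$ts, br$ts$cell_id),
                         function(d) c(diff(d$x), diff(d$y))))
  n <- length(steps)
  se <- 40 * sqrt(2 / (n - 1))          # chi-square sampling bound
  expect_lt(abs(mean(steps^2) - 40), 3 * se)

  still <- generate_trajectories(trajectory_phantom_spec(3L, "brownian", D = 0,
                                                         duration = 100, rng_seed = 1L))
  expect_true(all(still$ts$x == 0) && all(still$ts$y == 0))
})

test_that("trajectory spec validation rejects bad or mismatched parameters", {
  expect_error(trajectory_phantom_spec(10L, "brownian", D = -1), ">= 0")
  expect_error(trajectory_phantom_spec(10L, "brownian"), "requires 'D'")
  expect_error(trajectory_phantom_spec(10L, "fixed_step", step_length = 4, D = 1),
               "not used by mode")
  expect_error(trajectory_phantom_spec(10L, "prw", v = 1), "requires 'P'")
})

test_that("persistent random walk follows the Fuerth MSD with D = v^2 P / 2", {
  v <- 0.5; P <- 60
  tp <- generate_trajectories(trajectory_phantom_spec(400L, "prw", v = v, P = P,
                                                      duration = 1000,
                                                      frame_interval = 20,
                                                      rng_seed = 21L))
  msd <- compute_msd(tp$ts, max_lag_fraction = 0.3)
  D <- v^2 * P / 2
  furth <- 4 * D * (msd$lag - P * (1 - exp(-msd$lag / P)))
  rel <- abs(msd$msd[-1L] - furth[-1L]) / furth[-1L]
  expect_lt(max(rel), 0.12)
})

test_that("shape phantom reproduces requested aspect ratios in the rendered image", {
  circ <- generate_shape_image(shape_phantom_spec(5L, ar_values = 1,
                                                  image_shape = c(256L, 256L),
                                                  rng_seed = 3L))
  rec <- shape_records(circ$image, circ$pixel_size)
  expect_equal(nrow(rec), 5L)
  expect_true(all(abs(rec$aspect_ratio - 1) < 0.02))

  two <- generate_shape_image(shape_phantom_spec(2L, ar_values = c(3, 1.5),
                                                 image_shape = c(256L, 256L),
                                                 rng_seed = 5L))
  rec2 <- shape_records(two$image, two$pixel_size)
  expect_equal(sort(rec2$aspect_ratio), sort(two$sidecar$aspect_ratio),
               tolerance = 0.05)
})

test_that("mixture calibration hits the target AR fraction (binomial bound)", {
  mix <- ar_mixture_for_fraction(0.5)
  sh <- generate_shape_image(shape_phantom_spec(
    1000L, ar_mixture = mix, cell_area = 40, image_shape = c(2048L, 2048L),
    pixel_size = 1, rng_seed = 9L))
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(mean(sh$sidecar$aspect_ratio >= 2) - 0.5), 3 * se)
})

test_that("shape placement fails cleanly when cells cannot fit", {
  expect_error(generate_shape_image(shape_phantom_spec(50L, ar_values = 2,
                                                       image_shape = c(64L, 64L),
                                                       rng_seed = 1L)),
               "non-overlapping")
})

test_that("marker z-stack conserves total signal above background", {
  spec <- stack_phantom_spec(n_positive_cells = 10L, per_cell_intensity = 1000,
                             background_level = 5, noise_sd = 0, rng_seed = 6L)
  z <- generate_marker_zstack(spec, quantize = FALSE)
  expect_equal(sum(z$zstack - 5), 10 * 1000, tolerance = 1e-9)
  # conserved under z-permutation
  perm <- z$zstack[, , c(3, 1, 6, 2, 5, 4)]
  expect_equal(sum_project(perm), sum_project(z$zstack), tolerance = 1e-12)
  # empty stack has no signal
  z0 <- generate_marker_zstack(stack_phantom_spec(n_positive_cells = 0L,
                                                  background_level = 5,
                                                  rng_seed = 1L), quantize = FALSE)
  expect_equal(sum(z0$zstack - 5), 0, tolerance = 1e-9)
})
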