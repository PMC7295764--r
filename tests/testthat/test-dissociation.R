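# Radial profiling and Gaussian spheroid sizing.

gaussian_blob <- function(n, ps, cx, cy, sigma, A = 100) {
  x <- (seq_len(n) - 1L) * ps
  outer(exp(-(x - cy)^2 / (2 * sigma^2)), exp(-(x - cx)^2 / (2 * sigma^2))) * A
}

test_that("centroid finds a symmetric blob and shifts with translation", {
  ps <- 1
  img <- gaussian_blob(101, ps, cx = 50, cy = 50, sigma = 8)
  s <- image_series(img, ps, 20)
  ctr <- find_spheroid_center(s)
  expect_lt(max(abs(ctr - c(50, 50))), ps / 2)

  img2 <- gaussian_blob(101, ps, cx = 57, cy = 46, sigma = 8)
  ctr2 <- find_spheroid_center(image_series(img2, ps, 20))
  expect_equal(unname(ctr2 - ctr), c(7, -4), tolerance = 1e-6)
})

test_that("centroid of an asymmetric two-blob image matches the per-pixel oracle", {
  ps <- 0.8
  img <- gaussian_blob(101, ps, 20, 30, 5, A = 120) +
    gaussian_blob(101, ps, 60, 55, 9, A = 40)
  ctr <- find_spheroid_center(image_series(img, ps, 20))
  # brute-force oracle with the same background rule
  bg <- median(sort(as.numeric(img))[seq_len(floor(length(img) * 0.05))])
  w <- pmax(img - bg, 0)
  ox <- oy <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    ox <- ox + w[i, j] * (j - 1) * ps
    oy <- oy + w[i, j] * (i - 1) * ps
  }
  expect_equal(unname(ctr), c(ox, oy) / sum(w), tolerance = 1e-12)
  expect_error(find_spheroid_center(image_series(array(0, c(8, 8, 1, 1)), 1, 20)),
               "no signal")
})

test_that("radial profile of a constant image is flat and rotation-invariant", {
  img <- matrix(7, 101, 101)
  p <- radial_density_profile(img, 1, c(50, 50), bin_width = 2)
  expect_true(all(p$density[p$n_pixels > 0] == 7))
  expect_true(all(is.na(p$density[p$n_pixels == 0])))

  set.seed(3)
  img2 <- gaussian_blob(101, 1, 50, 50, 10) + matrix(runif(101^2), 101)
  p1 <- radial_density_profile(img2, 1, c(50, 50), bin_width = 2)
  # rotating the image by 90 degrees about the centre permutes pixels within
  # annuli only
  rot <- t(img2)[, rev(seq_len(101))]
  p2 <- radial_density_profile(rot, 1, c(50, 50), bin_width = 2)
  expect_equal(p1$density, p2$density, tolerance = 1e-12)
  expect_error(radial_density_profile(img, 1, c(50, 50), bin_width = 0), "bin_width")
  expect_error(radial_density_profile(img, 1, c(500, 50)), "inside the field")
})

test_that("radial profile matches the analytic curve and the per-pixel oracle", {
  ps <- 1
  x <- (0:100) * ps
  img <- outer(exp(-(x - 50)^2 / 200), exp(-(x - 50)^2 / 200))  # exp(-r^2/200)
  p <- radial_density_profile(img, ps, c(50, 50), bin_width = 2, max_radius = 40)
  ok <- p$n_pixels > 0
  expect_equal(p$density[ok], exp(-p$r[ok]^2 / 200), tolerance = 0.02)
  o <- naive_radial_profile(img, ps, c(50, 50), bin_width = 2, max_radius = 40)
  expect_equal(p$density, o$density, tolerance = 1e-12)
  expect_equal(p$n_pixels, o$n_pixels)
})

test_that("noiseless Gaussian profile is recovered to high precision", {
  r <- seq(1, 199, by = 2)
  prof <- structure(data.frame(r = r, density = 100 * exp(-r^2 / (2 * 50^2)),
                               n_pixels = rep(10L, length(r))),
                    class = c("radial_profile", "data.frame"))
  f <- fit_gaussian_sigma(prof)
  expect_true(f$converged)
  expect_equal(f$sigma, 50, tolerance = 1e-6)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$baseline, 0, tolerance = 1e-4)
  expect_error(fit_gaussian_sigma(prof[1:5, ]), "8 populated bins")
})

test_that("noisy-profile fit agrees with an exhaustive grid-search oracle", {
  set.seed(42)
  r <- seq(1, 199, by = 2)
  dens <- 100 * exp(-r^2 / (2 * 40^2)) + 5 + rnorm(length(r), sd = 10)
  prof <- structure(data.frame(r = r, density = dens,
                               n_pixels = rep(10L, length(r))),
                    class = c("radial_profile", "data.frame"))
  f <- fit_gaussian_sigma(prof)
  g <- grid_gaussian_fit(prof, A_range = c(50, 150), s_range = c(20, 60),
                         B_range = c(-5, 15))
  expect_equal(f$sigma, g$s, tolerance = 0.05)
  expect_equal(f$amplitude, g$A, tolerance = 0.05)
  expect_lt(abs(f$baseline - g$B), 2)
})

test_that("profile and fit are invariant under global intensity scaling", {
  ph <- generate_spheroid_timelapse(phantom_spec(
    image_shape = c(256L, 256L), pixel_size = 1.3, n_frames = 1L, rng_seed = 4L,
    channels = list(g = spheroid_phantom_spec(n_cells = 200L, sigma0 = 25,
                                              noise_sd = 0))))
  img <- ph$series$pixels[, , 1L, 1L]
  ctr <- ph$sidecar$center
  f1 <- fit_gaussian_sigma(radial_density_profile(img, 1.3, ctr))
  f2 <- fit_gaussian_sigma(radial_density_profile(img * 3, 1.3, ctr))
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
  expect_equal(f2$amplitude, 3 * f1$amplitude, tolerance = 1e-6)
})

test_that("fitted sigma converges to the true cloud scale at large n", {
  ph <- generate_spheroid_timelapse(phantom_spec(
    image_shape = c(512L, 512L), pixel_size = 1.3, n_frames = 1L, rng_seed = 8L,
    channels = list(g = spheroid_phantom_spec(n_cells = 1000L, sigma0 = 40,
                                              cell_radius = 3, noise_sd = 0))))
  f <- fit_gaussian_sigma(radial_density_profile(
    ph$series$pixels[, , 1L, 1L], 1.3, ph$sidecar$center))
  expect_lt(abs(f$sigma - 40) / 40, 0.05)
})

test_that("size series is flat for a static spheroid and anchored at 1", {
  ph <- generate_spheroid_timelapse(phantom_spec(
    image_shape = c(256L, 256L), pixel_size = 1.3, n_frames = 4L, rng_seed = 6L,
    channels = list(g = spheroid_phantom_spec(n_cells = 200L, sigma0 = 20))))
  ss <- size_series(ph$series, "g")
  expect_identical(ss$normalized_size[1L], 1)
  expect_true(all(abs(ss$normalized_size - 1) < 0.05))
})

test_that("size series recovers a fold-3 schedule and is monotone under growth", {
  folds <- vapply(1:5, function(seed) {
    ph <- generate_spheroid_timelapse(phantom_spec(
      image_shape = c(384L, 384L), pixel_size = 1.3, n_frames = 8L,
      rng_seed = seed,
      channels = list(g = spheroid_phantom_spec(n_cells = 300L, sigma0 = 25,
                                                fold_final = 3))))
    ss <- size_series(ph$series, "g")
    rho <- cor(ss$time_min, ss$sigma, method = "spearman")
    expect_gt(rho, 0.9)
    ss$normalized_size[nrow(ss)]
  }, numeric(1))
  expect_lt(abs(mean(folds) - 3) / 3, 0.1)
})

test_that("normalized size does not depend on the pixel scale", {
  ph <- generate_spheroid_timelapse(phantom_spec(
    image_shape = c(256L, 256L), pixel_size = 1.3, n_frames = 3L, rng_seed = 2L,
    channels = list(g = spheroid_phantom_spec(n_cells = 250L, sigma0 = 20,
                                              fold_final = 2))))
  s1 <- size_series(ph$series, "g")
  # reinterpret the same pixels at half the physical scale
  s2series <- image_series(ph$series$pixels, 0.65, 20, "g")
  s2 <- size_series(s2series, "g")
  expect_equal(s2$normalized_size, s1$normalized_size, tolerance = 0.02)
})

test_that("about 39% of an isotropic Gaussian cloud lies within one sigma", {
  ph <- generate_spheroid_timelapse(phantom_spec(
    image_shape = c(256L, 256L), pixel_size = 1.3, n_frames = 1L, rng_seed = 3L,
    channels = list(g = spheroid_phantom_spec(n_cells = 2000L, sigma0 = 20))))
  pos <- ph$sidecar$positions
  ctr <- ph$sidecar$center
  frac <- mean(sqrt((pos$x - ctr[1L])^2 + (pos$y - ctr[2L])^2) <= 20)
  expect_equal(frac, 1 - exp(-0.5), tolerance = 0.05)
})

test_that("dissociated singles are counted against the sidecar", {
  base <- function(detach, seed) phantom_spec(
    image_shape = c(384L, 384L), pixel_size = 1.3, n_frames = 1L, rng_seed = seed,
    channels = list(g = spheroid_phantom_spec(n_cells = 60L, sigma0 = 12,
                                              detach_fraction = detach,
                                              noise_sd = 0)))
  core <- generate_spheroid_timelapse(base(0, 1L))
  n0 <- count_dissociated_singles(core$series$pixels[, , 1L, 1L], 1.3,
                                  core$sidecar$center, sigma0 = 12)
  expect_equal(as.integer(n0), 0L)

  # seed chosen so the 12 seeded singles are mutually resolvable (> 25 um)
  det <- generate_spheroid_timelapse(base(0.2, 3L))
  sing <- det$sidecar$positions[det$sidecar$positions$detached, ]
  expect_gt(min(dist(cbind(sing$x, sing$y))), 25)
  n12 <- count_dissociated_singles(det$series$pixels[, , 1L, 1L], 1.3,
                                   det$sidecar$center, sigma0 = 12)
  expect_equal(as.integer(n12), 12L)

  # touching singles merge into one oversize component and undercount
  merged <- generate_spheroid_timelapse(base(0.2, 2L))
  nm <- count_dissociated_singles(merged$series$pixels[, , 1L, 1L], 1.3,
                                  merged$sidecar$center, sigma0 = 12)
  expect_equal(as.integer(nm), 11L)

  flow <- generate_spheroid_timelapse(base(0.5, 3L))
  ctrl <- generate_spheroid_timelapse(base(0.05, 3L))
  nf <- count_dissociated_singles(flow$series$pixels[, , 1L, 1L], 1.3,
                                  flow$sidecar$center, sigma0 = 12)
  nc <- count_dissociated_singles(ctrl$series$pixels[, , 1L, 1L], 1.3,
                                  ctrl$sidecar$center, sigma0 = 12)
  expect_gt(as.integer(nf), as.integer(nc))

  expect_warning(
    n_empty <- count_dissociated_singles(matrix(0, 64, 64), 1, c(32, 32), 5),
    "empty segmentation")
  expect_equal(as.integer(n_empty), 0L)
})
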