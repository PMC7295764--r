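# Synthetic phantom generators. Every input the pipeline consumes can be
# produced here with known ground truth, so each estimator is validated
# against the sidecar rather than against another estimate.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Add Gaussian spots to a matrix. Positions in 0-based pixel units
# (x = column, y = row); each spot is normalised over its rendered patch so
# it integrates to `totals[i]` counts. Returns the flags of clipped spots.
render_gaussian_spots <- function(img, x_px, y_px, sigma_px, totals) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(4 * sigma_px)
  clipped <- logical(length(x_px))
  for (i in seq_along(x_px)) {
    ci <- round(x_px[i]); ri <- round(y_px[i])
    c0 <- ci - half; c1 <- ci + half; r0 <- ri - half; r1 <- ri + half
    clipped[i] <- c0 < 0 || r0 < 0 || c1 > nc - 1L || r1 > nr - 1L
    if (c0 > nc - 1L || c1 < 0L || r0 > nr - 1L || r1 < 0L) next
    cc <- max(c0, 0L):min(c1, nc - 1L)
    rr <- max(r0, 0L):min(r1, nr - 1L)
    gx <- exp(-(cc - x_px[i])^2 / (2 * sigma_px^2))
    gy <- exp(-(rr - y_px[i])^2 / (2 * sigma_px^2))
    w <- outer(gy, gx)
    img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] + totals[i] * w / sum(w)
  }
  list(img = img, clipped = clipped)
}

quantize_counts <- function(img) pmin(pmax(round(img), 0), 65535)

#' Generate a dissociating-spheroid time-lapse phantom
#'
#' Each channel's population is a 2D Gaussian cell cloud: per-cell offsets are
#' drawn once from a standard isotropic Gaussian and scaled by the schedule
#' `sigma(t)`, which interpolates linearly from `sigma0` to
#' `fold_final * sigma0` over the acquisition, so cells move smoothly outward
#' as the spheroid dissociates and the positions at every frame are an exact
#' draw from an isotropic Gaussian of scale `sigma(t)`. A `detach_fraction` of
#' cells is instead re-seeded uniformly in the annulus from `3 * sigma0` to
#' the field edge as isolated singles. Cells are rendered as Gaussian spots of
#' scale `cell_radius`, Gaussian camera noise is added, and counts are
#' quantised to the 16-bit range.
#'
#' @param spec a [phantom_spec()] whose `channels` are
#'   [spheroid_phantom_spec()] objects.
#' @return list with `series` (an [image_series()]) and `sidecar`: the seed,
#'   per-channel `sigma_schedule` (data frame: channel, frame, sigma),
#'   `positions` (channel, cell_id, frame, x, y in um, detached, clipped) and
#'   the field centre in um.
#' @export
generate_spheroid_timelapse <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), length(spec$channels) >= 1L)
  for (ch in spec$channels) stopifnot(inherits(ch, "spheroid_phantom_spec"))
  shp <- spec$image_shape; ps <- spec$pixel_size; nf <- spec$n_frames
  center <- (shp[c(2L, 1L)] - 1L) / 2 * ps  # (x, y) um at field centre
  chn <- names(spec$channels) %||% paste0("ch", seq_along(spec$channels))
  if (is.null(names(spec$channels))) names(spec$channels) <- chn

  with_seed(spec$rng_seed, {
    px <- array(0, c(shp[1L], shp[2L], nf, length(spec$channels)))
    sched <- list(); pos_all <- list()
    for (k in seq_along(spec$channels)) {
      cs <- spec$channels[[k]]
      n_det <- round(cs$detach_fraction * cs$n_cells)
      n_core <- cs$n_cells - n_det
      z <- matrix(stats::rnorm(2L * n_core), ncol = 2L)
      # detached singles: uniform in annulus [3 sigma0, field edge]
      r_max <- min(center[1L], center[2L]) - 4 * cs$cell_radius
      r_min <- min(3 * cs$sigma0, r_max)
      r_det <- sqrt(stats::runif(n_det, r_min^2, r_max^2))
      th_det <- stats::runif(n_det, 0, 2 * pi)
      det_xy <- cbind(center[1L] + r_det * cos(th_det),
                      center[2L] + r_det * sin(th_det))
      sig <- if (nf == 1L) cs$sigma0 else
        cs$sigma0 * (1 + (cs$fold_final - 1) * (seq_len(nf) - 1L) / (nf - 1L))
      sched[[k]] <- data.frame(channel = chn[k], frame = seq_len(nf) - 1L,
                               sigma = sig)
      pos_ch <- vector("list", nf)
      for (fr in seq_len(nf)) {
        xy <- rbind(cbind(center[1L] + sig[fr] * z[, 1L],
                          center[2L] + sig[fr] * z[, 2L]),
                    det_xy)
        res <- render_gaussian_spots(px[, , fr, k], xy[, 1L] / ps, xy[, 2L] / ps,
                                     cs$cell_radius / ps,
                                     rep(cs$cell_intensity, nrow(xy)))
        img <- res$img
        if (cs$noise_sd > 0) {
          img <- img + stats::rnorm(length(img), sd = cs$noise_sd)
        }
        px[, , fr, k] <- quantize_counts(img)
        pos_ch[[fr]] <- data.frame(
          channel = chn[k], cell_id = seq_len(cs$n_cells), frame = fr - 1L,
          x = xy[, 1L], y = xy[, 2L],
          detached = c(rep(FALSE, n_core), rep(TRUE, n_det)),
          clipped = res$clipped)
      }
      pos_all[[k]] <- do.call(rbind, pos_ch)
    }
    list(series = image_series(px, ps, spec$frame_interval, chn),
         sidecar = list(rng_seed = spec$rng_seed, center = center,
                        sigma_schedule = do.call(rbind, sched),
                        positions = do.call(rbind, pos_all)))
  })
}

#' Generate random-walk cell trajectories
#'
#' Samples trajectories at `frame_interval` spacing according to the spec's
#' motility mode (see [trajectory_phantom_spec()]). Brownian steps are i.i.d.
#' Gaussian per axis with variance `2 D dt`; fixed-step displacements have
#' exactly the requested magnitude; the persistent random walk integrates an
#' Ornstein-Uhlenbeck velocity at 20 internal substeps per frame so its
#' ensemble MSD follows the Fuerth form.
#'
#' @param spec a [trajectory_phantom_spec()].
#' @return list with `ts` (a [trajectory_set()], all tracks starting at the
#'   origin) and `sidecar` recording the spec and the ground-truth speed
#'   and/or diffusion coefficient.
#' @export
generate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "trajectory_phantom_spec"))
  dt <- spec$frame_interval
  n_steps <- max(1L, round(spec$duration / dt))
  n <- spec$n_cells
  with_seed(spec$rng_seed, {
    tracks <- switch(spec$mode,
      brownian = {
        sd_step <- sqrt(2 * spec$D * dt)
        lapply(seq_len(n), function(i) {
          cbind(cumsum(c(0, stats::rnorm(n_steps, sd = sd_step))),
                cumsum(c(0, stats::rnorm(n_steps, sd = sd_step))))
        })
      },
      fixed_step = lapply(seq_len(n), function(i) {
        th <- stats::runif(n_steps, 0, 2 * pi)
        cbind(cumsum(c(0, spec$step_length * cos(th))),
              cumsum(c(0, spec$step_length * sin(th))))
      }),
      prw = {
        nsub <- 20L; dts <- dt / nsub
        sv <- spec$v / sqrt(2)           # per-axis stationary velocity sd
        a <- exp(-dts / spec$P)
        lapply(seq_len(n), function(i) {
          vs <- matrix(0, n_steps * nsub + 1L, 2L)
          vs[1L, ] <- stats::rnorm(2L, sd = sv)
          xi <- matrix(stats::rnorm(2L * n_steps * nsub, sd = sv * sqrt(1 - a^2)),
                       ncol = 2L)
          for (j in seq_len(n_steps * nsub)) vs[j + 1L, ] <- vs[j, ] * a + xi[j, ]
          disp <- vs[seq_len(n_steps * nsub), , drop = FALSE] * dts
          xy <- rbind(c(0, 0), apply(disp, 2L, cumsum))
          xy[seq(1L, n_steps * nsub + 1L, by = nsub), , drop = FALSE]
        })
      })
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(cell_id = i, frame = 0:n_steps,
                 x = tracks[[i]][, 1L], y = tracks[[i]][, 2L])
    }))
    truth <- switch(spec$mode,
      brownian = list(D = spec$D),
      fixed_step = list(speed = spec$step_length / dt,
                        step_length = spec$step_length),
      prw = list(v = spec$v, P = spec$P, D = spec$v^2 * spec$P / 2))
    list(ts = trajectory_set(df, dt),
         sidecar = c(list(rng_seed = spec$rng_seed, mode = spec$mode,
                          n_cells = n, duration = n_steps * dt), truth))
  })
}

#' Generate an image of non-overlapping elliptical cells
#'
#' Aspect ratios come from the spec (explicit values or a two-component
#' lognormal mixture); orientations are uniform; placement is random
#' sequential with overlap rejection (bounded retries, then failure). Cells
#' are filled ellipses of constant intensity on a zero background, optionally
#' with additive Gaussian noise.
#'
#' @param spec a [shape_phantom_spec()].
#' @return list with `image` (matrix of counts), `pixel_size`, and `sidecar`
#'   data frame: cell_id, x, y (um), semi_major, semi_minor (um), theta
#'   (radians), aspect_ratio.
#' @export
generate_shape_image <- function(spec) {
  stopifnot(inherits(spec, "shape_phantom_spec"))
  ps <- spec$pixel_size; shp <- spec$image_shape
  with_seed(spec$rng_seed, {
    ar <- if (!is.null(spec$ar_values)) {
      rep_len(spec$ar_values, spec$n_cells)
    } else {
      m <- spec$ar_mixture
      comp <- sample(1:2, spec$n_cells, replace = TRUE, prob = m$weights)
      pmax(1, stats::rlnorm(spec$n_cells, m$meanlog[comp], m$sdlog[comp]))
    }
    semi_minor <- sqrt(spec$cell_area / (pi * ar))
    semi_major <- ar * semi_minor
    theta <- stats::runif(spec$n_cells, 0, pi)
    xs <- ys <- numeric(spec$n_cells)
    margin <- 2 * ps
    for (i in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        x <- stats::runif(1, semi_major[i] + margin,
                          (shp[2L] - 1L) * ps - semi_major[i] - margin)
        y <- stats::runif(1, semi_major[i] + margin,
                          (shp[1L] - 1L) * ps - semi_major[i] - margin)
        if (i == 1L || all(sqrt((xs[seq_len(i - 1L)] - x)^2 +
                                (ys[seq_len(i - 1L)] - y)^2) >
                           semi_major[seq_len(i - 1L)] + semi_major[i] + margin)) {
          xs[i] <- x; ys[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place ", spec$n_cells,
                        " non-overlapping cells; reduce n_cells or cell_area")
    }
    img <- matrix(0, shp[1L], shp[2L])
    for (i in seq_len(spec$n_cells)) {
      half <- ceiling(semi_major[i] / ps) + 1L
      ci <- round(xs[i] / ps); ri <- round(ys[i] / ps)
      cc <- max(ci - half, 0L):min(ci + half, shp[2L] - 1L)
      rr <- max(ri - half, 0L):min(ri + half, shp[1L] - 1L)
      dx <- outer(rep(1, length(rr)), cc * ps - xs[i])
      dy <- outer(rr * ps - ys[i], rep(1, length(cc)))
      u <- (dx * cos(theta[i]) + dy * sin(theta[i])) / semi_major[i]
      v <- (-dx * sin(theta[i]) + dy * cos(theta[i])) / semi_minor[i]
      inside <- (u^2 + v^2) <= 1
      img[rr + 1L, cc + 1L][inside] <- spec$cell_intensity
    }
    if (spec$noise_sd > 0) img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    list(image = quantize_counts(img), pixel_size = ps,
         sidecar = data.frame(cell_id = seq_len(spec$n_cells), x = xs, y = ys,
                              semi_major = semi_major, semi_minor = semi_minor,
                              theta = theta, aspect_ratio = ar))
  })
}

#' Calibrate a two-component aspect-ratio mixture to a target fraction
#'
#' Solves for the mixture weight of an elongated and a rounded lognormal
#' component so that the expected fraction of cells with aspect ratio at or
#' above `threshold` equals `target`. Used to build shape phantoms whose true
#' mesenchymal fraction matches a prescribed value.
#'
#' @param target desired expected fraction with AR >= threshold.
#' @param meanlog,sdlog length-2 lognormal parameters for the elongated and
#'   rounded components.
#' @param threshold classification threshold (default 2).
#' @return an `ar_mixture` list for [shape_phantom_spec()].
#' @export
ar_mixture_for_fraction <- function(target, meanlog = c(log(3), log(1.4)),
                                    sdlog = c(0.25, 0.2), threshold = 2) {
  p <- 1 - stats::plnorm(threshold, meanlog, sdlog)
  if (target > max(p) || target < min(p))
    stop(sprintf("target %.3g outside achievable range [%.3g, %.3g]",
                 target, min(p), max(p)))
  w <- (target - p[2L]) / (p[1L] - p[2L])
  list(meanlog = meanlog, sdlog = sdlog, weights = c(w, 1 - w))
}

#' Generate a confocal marker z-stack phantom
#'
#' Positive cells are placed uniformly in the field (away from the border so
#' no signal is clipped); each cell's integrated intensity is split across
#' slices with a Gaussian axial profile and rendered as an xy Gaussian spot,
#' both normalised exactly so that before noise and quantisation the total
#' signal above background equals `n_positive_cells * per_cell_intensity`.
#'
#' @param spec a [stack_phantom_spec()].
#' @param quantize round to integer counts (default TRUE, the camera model);
#'   set FALSE for exact conservation checks.
#' @return list with `zstack` (array row x col x slice), `pixel_size`, and
#'   `sidecar`: per-cell positions, centre slice and integrated intensity,
#'   plus the true background level.
#' @export
generate_marker_zstack <- function(spec, quantize = TRUE) {
  stopifnot(inherits(spec, "stack_phantom_spec"))
  shp <- spec$image_shape; ps <- spec$pixel_size
  with_seed(spec$rng_seed, {
    stack <- array(spec$background_level, c(shp[1L], shp[2L], spec$n_slices))
    n <- spec$n_positive_cells
    margin <- 5 * spec$cell_radius
    if (n > 0L) {
      xs <- stats::runif(n, margin, (shp[2L] - 1L) * ps - margin)
      ys <- stats::runif(n, margin, (shp[1L] - 1L) * ps - margin)
      zc <- stats::runif(n, 1, spec$n_slices)       # centre slice, continuous
      for (i in seq_len(n)) {
        wz <- stats::dnorm(seq_len(spec$n_slices), zc[i], 1)
        wz <- wz / sum(wz)                          # exact axial normalisation
        for (s in seq_len(spec$n_slices)) {
          res <- render_gaussian_spots(stack[, , s], xs[i] / ps, ys[i] / ps,
                                       spec$cell_radius / ps,
                                       spec$per_cell_intensity * wz[s])
          stack[, , s] <- res$img
        }
      }
      sidecar <- data.frame(cell_id = seq_len(n), x = xs, y = ys, z_center = zc,
                            integrated_intensity = rep(spec$per_cell_intensity, n))
    } else {
      sidecar <- data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                            z_center = numeric(), integrated_intensity = numeric())
    }
    if (spec$noise_sd > 0) {
      stack <- stack + stats::rnorm(length(stack), sd = spec$noise_sd)
    }
    if (quantize) stack <- quantize_counts(stack)
    list(zstack = stack, pixel_size = ps,
         sidecar = list(cells = sidecar, background_level = spec$background_level,
                        rng_seed = spec$rng_seed))
  })
}

#' Render a trajectory set into a time-lapse movie
#'
#' Each tracked cell becomes a Gaussian spot at its position in every frame.
#' Used to validate the detector/linker against known track identities.
#'
#' @param ts a [trajectory_set()] with positions in um (positions must fit in
#'   the field).
#' @param image_shape c(rows, cols) pixels.
#' @param pixel_size um/pixel.
#' @param spot_sigma rendered spot scale, um.
#' @param cell_intensity integrated counts per spot.
#' @param noise_sd additive Gaussian noise, counts.
#' @param channel_name label for the single rendered channel.
#' @param rng_seed seed for the noise.
#' @return an [image_series()].
#' @export
render_tracks_movie <- function(ts, image_shape = c(256L, 256L), pixel_size = 0.65,
                                spot_sigma = 2, cell_intensity = 2000,
                                noise_sd = 0, channel_name = "green",
                                rng_seed = 1L) {
  frames <- sort(unique(ts$frame))
  if (!identical(frames, seq(min(frames), max(frames)))) {
    stop("movie rendering requires gap-free consecutive frames")
  }
  nf <- length(frames)
  px <- array(0, c(image_shape[1L], image_shape[2L], nf, 1L))
  with_seed(rng_seed, {
    for (k in seq_len(nf)) {
      sel <- ts$frame == frames[k]
      res <- render_gaussian_spots(px[, , k, 1L],
                                   ts$x[sel] / pixel_size, ts$y[sel] / pixel_size,
                                   spot_sigma / pixel_size,
                                   rep(cell_intensity, sum(sel)))
      img <- res$img
      if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
      px[, , k, 1L] <- quantize_counts(img)
    }
  })
  image_series(px, pixel_size, frame_interval_of(ts), channel_name)
}
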