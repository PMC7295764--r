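# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity with the most literal implementation available so
# the pipeline's vectorised estimators can be checked against them.

# MSD by explicit double loop over all record pairs within each cell
naive_msd <- function(ts, max_lag_fraction = 0.25) {
  dt <- attr(ts, "frame_interval")
  tracks <- split(ts[c("frame", "x", "y")], ts$cell_id)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= 2L]
  span <- max(vapply(tracks, function(d) diff(range(d$frame)), integer(1)))
  max_lag <- max(1L, floor(span * max_lag_fraction))
  ssq <- rep(0, max_lag); np <- rep(0, max_lag)
  for (d in tracks) {
    for (i in seq_len(nrow(d) - 1L)) {
      for (j in (i + 1L):nrow(d)) {
        L <- d$frame[j] - d$frame[i]
        if (L <= max_lag) {
          ssq[L] <- ssq[L] + (d$x[j] - d$x[i])^2 + (d$y[j] - d$y[i])^2
          np[L] <- np[L] + 1
        }
      }
    }
  }
  keep <- np > 0
  data.frame(lag = seq_len(max_lag)[keep] * dt, msd = ssq[keep] / np[keep],
             n_pairs = np[keep])
}

# radial profile by explicit per-pixel loop
naive_radial_profile <- function(frame, pixel_size, center, bin_width,
                                 max_radius) {
  nb <- floor(max_radius / bin_width) + 1L
  sums <- rep(0, nb); cnts <- rep(0L, nb)
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      r <- sqrt(((j - 1) * pixel_size - center[1L])^2 +
                ((i - 1) * pixel_size - center[2L])^2)
      b <- floor(r / bin_width) + 1L
      if (b <= nb) { sums[b] <- sums[b] + frame[i, j]; cnts[b] <- cnts[b] + 1L }
    }
  }
  data.frame(r = (seq_len(nb) - 0.5) * bin_width,
             density = ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_),
             n_pixels = cnts)
}

# Gaussian profile fit by exhaustive grid search over (A, sigma, B)
grid_gaussian_fit <- function(profile, A_range, s_range, B_range, n = 61L) {
  d <- profile[!is.na(profile$density), ]
  grid <- expand.grid(A = seq(A_range[1L], A_range[2L], length.out = n),
                      s = seq(s_range[1L], s_range[2L], length.out = n),
                      B = seq(B_range[1L], B_range[2L], length.out = 21L))
  sse <- vapply(seq_len(nrow(grid)), function(k) {
    sum((d$density - grid$A[k] * exp(-d$r^2 / (2 * grid$s[k]^2)) - grid$B[k])^2)
  }, numeric(1))
  grid[which.min(sse), ]
}

# small brownian trajectory set built directly (bypasses the generator)
tiny_brownian_ts <- function(n_cells, n_steps, D, dt, seed) {
  set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  df <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    data.frame(cell_id = i, frame = 0:n_steps,
               x = cumsum(c(0, rnorm(n_steps, sd = sd_step))),
               y = cumsum(c(0, rnorm(n_steps, sd = sd_step))))
  }))
  trajectory_set(df, dt)
}

# analytic-ellipse pixel mask centred in a matrix
ellipse_mask <- function(nrow, ncol, semi_major, semi_minor, theta = 0) {
  cy <- (nrow - 1) / 2; cx <- (ncol - 1) / 2
  m <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      dx <- (j - 1) - cx; dy <- (i - 1) - cy
      u <- (dx * cos(theta) + dy * sin(theta)) / semi_major
      v <- (-dx * sin(theta) + dy * cos(theta)) / semi_minor
      if (u^2 + v^2 <= 1) m[i, j] <- TRUE
    }
  }
  m
}
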