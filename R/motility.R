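# Cell motility statistics: speed, MSD, diffusion coefficient, flow-axis
# directional bias, plus a minimal spot detector / linker to obtain
# trajectories from movies.

#' Per-cell migration speed
#'
#' Speed of a track is the total path length divided by the tracked time:
#' `sum(|dr|) / (n_steps * dt)` where steps run between consecutive records
#' (a gap of g frames contributes g * dt to the denominator). Cells observed
#' in fewer than two frames are excluded and counted.
#'
#' @param ts a [trajectory_set()].
#' @return object of class `speed_summary`: list with `per_cell` (data frame
#'   cell_id, speed um/min, n_steps), `mean`, `sem`, `n`, `n_excluded`.
#' @export
compute_speed <- function(ts) {
  dt <- frame_interval_of(ts)
  per <- lapply(split(ts[c("frame", "x", "y")], ts$cell_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    path <- sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
    nsteps <- d$frame[nrow(d)] - d$frame[1L]
    c(speed = path / (nsteps * dt), n_steps = nsteps)
  })
  excluded <- sum(vapply(per, is.null, logical(1)))
  if (excluded > 0L) message(excluded, " single-frame cell(s) excluded from speed")
  keep <- !vapply(per, is.null, logical(1))
  pc <- data.frame(cell_id = names(per)[keep],
                   do.call(rbind, per[keep]), row.names = NULL)
  s <- summarize_mean_sem(pc$speed)
  structure(list(per_cell = pc, mean = s$mean, sem = s$sem,
                 n = nrow(pc), n_excluded = excluded),
            class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("<speed_summary> n = %d cells: mean speed %.4g +/- %.2g um/min (SEM)\n",
              x$n, x$mean, x$sem))
  invisible(x)
}

#' Ensemble mean squared displacement
#'
#' Time-averaged MSD within each cell (all start times, overlapping windows),
#' then ensemble-averaged across cells with per-lag pair-count weights - i.e.
#' the pooled mean of squared displacements over every available pair at each
#' lag. Tracks that start at different absolute times are aligned by
#' track-relative time. Lags are reported up to `max_lag_fraction` of the
#' longest track duration.
#'
#' @param ts a [trajectory_set()].
#' @param max_lag_fraction fraction of the maximum track duration up to which
#'   lags are reported (default 0.25, where time-averaged MSDs are
#'   statistically reliable).
#' @return object of class `msd_curve`: data frame with `lag` (minutes),
#'   `msd` (um^2), `n_pairs`. Lag 0 (msd 0) is included.
#' @export
compute_msd <- function(ts, max_lag_fraction = 0.25) {
  dt <- frame_interval_of(ts)
  tracks <- split(ts[c("frame", "x", "y")], ts$cell_id)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= 2L]
  if (length(tracks) == 0L) stop("need at least one cell with >= 2 frames")
  span <- max(vapply(tracks, function(d) diff(range(d$frame)), integer(1)))
  max_lag <- max(1L, floor(span * max_lag_fraction))
  ssq <- rep(0, max_lag); npair <- rep(0, max_lag)
  for (d in tracks) {
    # index positions by frame to honour gaps
    xs <- rep(NA_real_, diff(range(d$frame)) + 1L); ys <- xs
    off <- d$frame - d$frame[1L] + 1L
    xs[off] <- d$x; ys[off] <- d$y
    top <- length(xs)
    for (L in seq_len(min(max_lag, top - 1L))) {
      dx <- xs[(1L + L):top] - xs[1L:(top - L)]
      dy <- ys[(1L + L):top] - ys[1L:(top - L)]
      ok <- !is.na(dx)
      ssq[L] <- ssq[L] + sum(dx[ok]^2 + dy[ok]^2)
      npair[L] <- npair[L] + sum(ok)
    }
  }
  keep <- npair > 0
  structure(data.frame(lag = c(0, seq_len(max_lag)[keep] * dt),
                       msd = c(0, ssq[keep] / npair[keep]),
                       n_pairs = c(sum(vapply(tracks, nrow, integer(1))),
                                   npair[keep])),
            class = c("msd_curve", "data.frame"))
}

#' @export
plot.msd_curve <- function(x, log = "xy", ...) {
  d <- x[x$lag > 0, ]
  graphics::plot(d$lag, d$msd, log = log, xlab = "lag (min)",
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

#' Fit the diffusion coefficient from an MSD curve
#'
#' Weighted least squares of `msd = 4 D lag` through the origin (the
#' first-order 2D diffusion model; no intercept because the model has none),
#' with the per-lag pair counts as weights. The closed form is
#' `D = sum(w lag msd) / (4 sum(w lag^2))`.
#'
#' @param msd an [compute_msd()] curve (lag 0 is ignored).
#' @return object of class `diffusion_fit`: list with `D` (um^2/min), `se`,
#'   `n_lags`, and `negative_slope` warning flag.
#' @export
fit_diffusion_coefficient <- function(msd) {
  d <- msd[msd$lag > 0, ]
  if (nrow(d) < 3L) stop("need at least 3 positive lags")
  fit <- stats::lm(msd ~ 0 + lag, data = d, weights = d$n_pairs)
  D <- unname(stats::coef(fit)[1L]) / 4
  # suppressed: summary.lm warns on exactly linear input ("perfect fit")
  se <- suppressWarnings(summary(fit)$coefficients[1L, 2L]) / 4
  if (D < 0) warning("negative MSD slope; D reported as fitted")
  structure(list(D = D, se = se, n_lags = nrow(d), negative_slope = D < 0),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g um^2/min (%d lags)\n",
              x$D, x$se, x$n_lags))
  invisible(x)
}

#' Directional statistics along the flow axis
#'
#' For each cell, the net velocity along the flow axis
#' `Vx = (x_end - x_start) / duration` and the forward migration index
#' `Px = (x_end - x_start) / path_length` (in [-1, 1]); the flow axis is +x
#' after rotating coordinates by `-flow_angle`. A one-sample Student's t-test
#' of the per-cell Vx against zero asks whether migration is biased along the
#' flow.
#'
#' @param ts a [trajectory_set()].
#' @param flow_angle flow direction in radians from +x (default 0).
#' @return object of class `directional_stats`: list with `per_cell` (cell_id,
#'   Vx um/min, Px), group means/SEMs, `t_statistic`, `p_value`, `n`.
#' @export
directional_stats <- function(ts, flow_angle = 0) {
  dt <- frame_interval_of(ts)
  ca <- cos(-flow_angle); sa <- sin(-flow_angle)
  per <- lapply(split(ts[c("frame", "x", "y")], ts$cell_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    x <- d$x * ca - d$y * sa
    y <- d$x * sa + d$y * ca
    dur <- (d$frame[nrow(d)] - d$frame[1L]) * dt
    path <- sum(sqrt(diff(x)^2 + diff(y)^2))
    c(Vx = (x[length(x)] - x[1L]) / dur,
      Px = if (path > 0) (x[length(x)] - x[1L]) / path else NA_real_)
  })
  keep <- !vapply(per, is.null, logical(1))
  pc <- data.frame(cell_id = names(per)[keep],
                   do.call(rbind, per[keep]), row.names = NULL)
  tt <- tryCatch(stats::t.test(pc$Vx, mu = 0),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  sVx <- summarize_mean_sem(pc$Vx)
  px_ok <- pc$Px[!is.na(pc$Px)]
  sPx <- if (length(px_ok)) summarize_mean_sem(px_ok) else
    list(mean = NA_real_, sem = NA_real_)
  structure(list(per_cell = pc, mean_Vx = sVx$mean, sem_Vx = sVx$sem,
                 mean_Px = sPx$mean, sem_Px = sPx$sem,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 n = nrow(pc)),
            class = "directional_stats")
}

#' @export
print.directional_stats <- function(x, ...) {
  cat(sprintf(paste0("<directional_stats> n = %d cells\n",
                     "  Vx = %.4g +/- %.2g um/min, Px = %.3g +/- %.2g\n",
                     "  H0 Vx = 0: t = %.3g, p = %.3g\n"),
              x$n, x$mean_Vx, x$sem_Vx, x$mean_Px, x$sem_Px,
              x$t_statistic, x$p_value))
  invisible(x)
}

# ---- detection and linking -------------------------------------------------

# Laplacian-of-Gaussian spot detection on one frame; returns um coordinates.
detect_spots <- function(img, pixel_size, spot_sigma, threshold_quantile = 0.999,
                         mask_center = NULL, mask_radius = 0) {
  s_px <- spot_sigma / pixel_size
  half <- ceiling(4 * s_px)
  ax <- -half:half
  g <- exp(-ax^2 / (2 * s_px^2))
  G <- outer(g, g); G <- G / sum(G)
  # negative LoG kernel: bright blobs become positive peaks
  lap <- outer(ax^2, ax^2, `+`) / s_px^4 - 2 / s_px^2
  K <- -lap * G; K <- K - mean(K)
  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), K))
  thr <- stats::quantile(resp, threshold_quantile)
  thr <- max(thr, 1e-9)
  nr <- nrow(resp); nc <- ncol(resp)
  inner <- resp[2:(nr - 1L), 2:(nc - 1L)]
  ismax <- inner > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & inner >= resp[2:(nr - 1L) + dr, 2:(nc - 1L) + dc]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(data.frame(x = numeric(), y = numeric()))
  rows <- idx[, 1L] + 1L; cols <- idx[, 2L] + 1L
  # subpixel centroid refinement in a 5x5 window of the raw image
  xs <- ys <- numeric(length(rows))
  for (i in seq_along(rows)) {
    rr <- max(rows[i] - 2L, 1L):min(rows[i] + 2L, nr)
    cc <- max(cols[i] - 2L, 1L):min(cols[i] + 2L, nc)
    w <- img[rr, cc, drop = FALSE]
    w <- pmax(w - min(w), 0)
    tw <- sum(w)
    if (tw > 0) {
      ys[i] <- sum(rowSums(w) * (rr - 1L)) / tw
      xs[i] <- sum(colSums(w) * (cc - 1L)) / tw
    } else {
      ys[i] <- rows[i] - 1L; xs[i] <- cols[i] - 1L
    }
  }
  out <- data.frame(x = xs * pixel_size, y = ys * pixel_size)
  if (!is.null(mask_center) && mask_radius > 0) {
    keep <- sqrt((out$x - mask_center[1L])^2 + (out$y - mask_center[2L])^2) >
      mask_radius
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Detect and link cells into trajectories
#'
#' A minimal single-particle tracker for sparse cells outside the spheroid
#' core: Laplacian-of-Gaussian spot detection on every frame followed by
#' greedy mutual-nearest-neighbour frame-to-frame linking with a displacement
#' gate. No gap closing. Tracks shorter than `min_length` frames are dropped.
#' The dense core can be excluded by masking a disc around the spheroid
#' centre (typically `2 * sigma0`).
#'
#' @param series an [image_series()].
#' @param channel channel index or name.
#' @param spot_sigma expected spot scale, um.
#' @param gate maximum frame-to-frame displacement accepted as a link, um
#'   (default 4x the expected step; detections farther apart start new
#'   tracks, so an undersized gate fragments tracks).
#' @param expected_step expected displacement per frame, um (used only for
#'   the default gate).
#' @param min_length minimum track length in frames.
#' @param threshold_quantile detection threshold on the LoG response.
#' @param mask_center,mask_radius optional exclusion disc (um).
#' @return a [trajectory_set()] (empty, with a warning, if nothing was
#'   detected).
#' @export
detect_and_link <- function(series, channel = 1L, spot_sigma = 2,
                            expected_step = 4, gate = 4 * expected_step,
                            min_length = 5L, threshold_quantile = 0.999,
                            mask_center = NULL, mask_radius = 0) {
  nf <- dim(series$pixels)[3L]
  dets <- lapply(seq_len(nf) - 1L, function(fr)
    detect_spots(get_frame(series, fr, channel), series$pixel_size, spot_sigma,
                 threshold_quantile, mask_center, mask_radius))
  if (all(vapply(dets, nrow, integer(1)) == 0L)) {
    warning("no detections in any frame; empty trajectory set")
    return(trajectory_set(data.frame(cell_id = integer(), frame = integer(),
                                     x = numeric(), y = numeric()),
                          series$frame_interval))
  }
  next_id <- 1L
  track_of <- vector("list", nf)  # per frame: track id of each detection
  recs <- list()
  for (fr in seq_len(nf)) {
    d <- dets[[fr]]
    if (nrow(d) == 0L) { track_of[[fr]] <- integer(0); next }
    ids <- rep(NA_integer_, nrow(d))
    if (fr > 1L && length(track_of[[fr - 1L]]) > 0L) {
      prev <- dets[[fr - 1L]]
      dist <- outer(prev$x, d$x, `-`)^2 + outer(prev$y, d$y, `-`)^2
      dist <- sqrt(dist)
      # greedy linking by ascending distance within the gate; each accepted
      # pair is a mutual nearest neighbour among the remaining candidates
      repeat {
        m <- which.min(dist)
        if (length(m) == 0L || !is.finite(dist[m]) || dist[m] > gate) break
        pi <- (m - 1L) %% nrow(dist) + 1L
        ci <- (m - 1L) %/% nrow(dist) + 1L
        ids[ci] <- track_of[[fr - 1L]][pi]
        dist[pi, ] <- Inf; dist[, ci] <- Inf
      }
    }
    for (i in which(is.na(ids))) { ids[i] <- next_id; next_id <- next_id + 1L }
    track_of[[fr]] <- ids
    recs[[fr]] <- data.frame(cell_id = ids, frame = fr - 1L, x = d$x, y = d$y)
  }
  df <- do.call(rbind, recs)
  len <- table(df$cell_id)
  df <- df[df$cell_id %in% as.integer(names(len)[len >= min_length]), ,
           drop = FALSE]
  trajectory_set(df, series$frame_interval)
}
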