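# Spheroid dissociation quantification: radial density profiles, Gaussian
# sigma per frame, normalized size series, dissociated single-cell counts.

#' Locate the spheroid centre on frame 0
#'
#' Intensity-weighted centroid of the background-subtracted, channel-summed
#' first frame. The centre is determined once on frame 0 and held fixed for
#' all later frames, so the radial coordinate stays anchored to the initial
#' spheroid while it dissociates.
#'
#' @param series an [image_series()].
#' @param channels channels to sum (indices or names); default all.
#' @return c(x, y) in micrometres.
#' @export
find_spheroid_center <- function(series, channels = NULL) {
  chs <- if (is.null(channels)) seq_along(series$channel_names) else
    vapply(channels, resolve_channel, integer(1), series = series)
  img <- Reduce(`+`, lapply(chs, function(ch) get_frame(series, 0L, ch)))
  img <- subtract_background(img)
  tot <- sum(img)
  if (tot <= 0) stop("frame 0 has no signal above background")
  ps <- series$pixel_size
  cols <- (seq_len(ncol(img)) - 1L) * ps
  rows <- (seq_len(nrow(img)) - 1L) * ps
  c(x = sum(img %*% cols) / tot, y = sum(rows %*% img) / tot)
}

#' Radial cell-density profile
#'
#' Azimuthally averaged intensity as a function of radial distance from the
#' spheroid centre: pixels are assigned to annuli `[r, r + bin_width)` by the
#' distance of their centre from `center`, and the density in each annulus is
#' the mean pixel intensity there. Annuli containing no pixels are flagged
#' (`n_pixels = 0`, density `NA`), never interpolated.
#'
#' @param frame intensity matrix (one frame, one channel).
#' @param pixel_size um/pixel.
#' @param center c(x, y) in um, inside the field.
#' @param bin_width annulus width in um (default two pixels).
#' @param max_radius largest radius to profile; default the largest distance
#'   from the centre to a field corner.
#' @param frame_index stored for bookkeeping.
#' @return object of class `radial_profile`: data frame with columns `r` (bin
#'   centre, um), `density`, `n_pixels`.
#' @export
radial_density_profile <- function(frame, pixel_size, center,
                                   bin_width = 2 * pixel_size,
                                   max_radius = NULL, frame_index = 0L) {
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  ps <- pixel_size
  xmax <- (ncol(frame) - 1L) * ps; ymax <- (nrow(frame) - 1L) * ps
  if (center[1L] < 0 || center[1L] > xmax || center[2L] < 0 || center[2L] > ymax)
    stop("center must lie inside the field")
  geom <- radial_bin_geometry(dim(frame), ps, center, bin_width, max_radius)
  prof <- radial_bin_apply(frame, geom)
  structure(data.frame(r = prof$r, density = prof$density,
                       n_pixels = prof$n_pixels),
            center = center, frame_index = frame_index,
            bin_width = bin_width,
            class = c("radial_profile", "data.frame"))
}

#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$r, x$density, type = "l", xlab = "r (um)",
                 ylab = "mean intensity", ...)
  invisible(x)
}

# Precompute the annulus index of every pixel for a fixed centre; reused
# across the frames of a series. Annuli [r, r + bin_width) are open on the
# right; pixels beyond max_radius are dropped.
radial_bin_geometry <- function(shape, pixel_size, center, bin_width,
                                max_radius = NULL) {
  dx <- (seq_len(shape[2L]) - 1L) * pixel_size - center[1L]
  dy <- (seq_len(shape[1L]) - 1L) * pixel_size - center[2L]
  r <- sqrt(outer(dy^2, dx^2, `+`))
  if (is.null(max_radius)) max_radius <- max(r)
  idx <- floor(r / bin_width) + 1L
  nb <- floor(max_radius / bin_width) + 1L
  keep <- idx <= nb
  cnts <- tabulate(idx[keep], nb)
  list(idx = idx, keep = keep, nb = nb, n_pixels = cnts,
       r = (seq_len(nb) - 0.5) * bin_width)
}

radial_bin_apply <- function(frame, geom) {
  sums <- rep(0, geom$nb)
  rs <- rowsum(frame[geom$keep], geom$idx[geom$keep])
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  list(r = geom$r, n_pixels = geom$n_pixels,
       density = ifelse(geom$n_pixels > 0L, sums / pmax(geom$n_pixels, 1L),
                        NA_real_))
}

#' Fit a Gaussian to a radial density profile
#'
#' Nonlinear least squares of `density(r) = A exp(-r^2 / (2 sigma^2)) + B`,
#' weighted by the pixel count of each annulus (the variance of an azimuthal
#' mean scales inversely with the number of pixels averaged, so the few-pixel
#' innermost annuli carry proportionally less weight). The fitted sigma is
#' the spheroid size. The constant baseline absorbs the camera offset. Starting values: A at the maximum density, sigma at the
#' half-maximum radius, B at the median of the outer-20% tail; convergence
#' tolerance 1e-8, at most 1000 function evaluations. A non-converged fit is
#' returned flagged and must not be used downstream.
#'
#' @param profile a [radial_density_profile()].
#' @return object of class `gaussian_fit`: list with `amplitude`, `sigma`
#'   (um), `baseline`, `residual_norm`, `converged`.
#' @export
fit_gaussian_sigma <- function(profile) {
  d <- profile[!is.na(profile$density) & profile$n_pixels > 0L, ]
  if (nrow(d) < 8L) stop("need at least 8 populated bins")
  A0 <- max(d$density) - min(d$density)
  B0 <- stats::median(d$density[d$r >= stats::quantile(d$r, 0.8)])
  # sigma start from the radial second moment of the baseline-subtracted
  # profile (E r^2 = 2 sigma^2 for a 2D Gaussian); robust against noisy
  # single bins, unlike a half-maximum crossing
  w <- pmax(d$density - B0, 0)
  s0 <- sqrt(sum(w * d$r^3) / (2 * sum(w * d$r)))
  if (!is.finite(s0) || s0 <= 0) s0 <- stats::median(d$r)
  fit <- tryCatch(
    minpack.lm::nlsLM(density ~ A * exp(-r^2 / (2 * s^2)) + B, data = d,
                      weights = d$n_pixels,
                      start = list(A = A0, s = s0, B = B0),
                      lower = c(A = 0, s = 1e-6, B = -Inf),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-8, ptol = 1e-8, maxfev = 1000L, maxiter = 500L)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, sigma = NA_real_,
                          baseline = NA_real_, residual_norm = NA_real_,
                          converged = FALSE), class = "gaussian_fit"))
  }
  co <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  structure(list(amplitude = unname(co["A"]), sigma = abs(unname(co["s"])),
                 baseline = unname(co["B"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = isTRUE(conv)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gaussian_fit> NOT CONVERGED\n")
  } else {
    cat(sprintf("<gaussian_fit> A = %.4g, sigma = %.4g um, B = %.4g (rss %.3g)\n",
                x$amplitude, x$sigma, x$baseline, x$residual_norm))
  }
  invisible(x)
}

#' Spheroid size time series
#'
#' Fits the radial Gaussian on every frame of one channel (fixed frame-0
#' centre) and normalises sigma by its frame-0 value. The frame-0 fit must
#' converge (it anchors the normalisation); later non-converged fits are
#' reported as `NA` with a warning and dropped from downstream statistics
#' rather than imputed.
#'
#' @param series an [image_series()].
#' @param channel channel index or name.
#' @param bin_width annulus width in um.
#' @param center optional c(x, y) um; default [find_spheroid_center()] on the
#'   chosen channel.
#' @return object of class `size_series`: data frame with `frame`,
#'   `time_min`, `sigma`, `normalized_size`, `converged`.
#' @export
size_series <- function(series, channel = 1L, bin_width = 2 * series$pixel_size,
                        center = NULL) {
  nf <- dim(series$pixels)[3L]
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(center)) center <- find_spheroid_center(series, channels = channel)
  geom <- radial_bin_geometry(dim(series$pixels)[1:2], series$pixel_size,
                              center, bin_width)
  sig <- rep(NA_real_, nf); conv <- logical(nf)
  for (fr in seq_len(nf) - 1L) {
    p <- radial_bin_apply(get_frame(series, fr, channel), geom)
    prof <- structure(data.frame(r = p$r, density = p$density,
                                 n_pixels = p$n_pixels),
                      center = center, frame_index = fr,
                      bin_width = bin_width,
                      class = c("radial_profile", "data.frame"))
    f <- fit_gaussian_sigma(prof)
    conv[fr + 1L] <- f$converged
    if (f$converged) sig[fr + 1L] <- f$sigma
  }
  if (!conv[1L]) stop("frame-0 Gaussian fit failed: no normalization anchor")
  if (any(!conv)) warning(sum(!conv), " frame(s) had non-converged fits; reported NA")
  norm <- sig / sig[1L]
  norm[1L] <- 1                      # exact by definition
  structure(data.frame(frame = seq_len(nf) - 1L,
                       time_min = (seq_len(nf) - 1L) * series$frame_interval,
                       sigma = sig, normalized_size = norm, converged = conv),
            channel = series$channel_names[resolve_channel(series, channel)],
            center = center,
            class = c("size_series", "data.frame"))
}

#' @export
plot.size_series <- function(x, ...) {
  graphics::plot(x$time_min / 60, x$normalized_size, type = "l",
                 xlab = "time (h)", ylab = "normalized spheroid size", ...)
  invisible(x)
}

#' Count dissociated single cells in a frame
#'
#' Background-subtracts one channel of a frame, thresholds it with Otsu's
#' method, labels connected components, and counts components whose centroid
#' lies farther than `k * sigma0` from the spheroid centre and whose area
#' falls within single-cell bounds. The standard readout for how many cells
#' have left the spheroid core.
#'
#' @param frame intensity matrix.
#' @param pixel_size um/pixel.
#' @param center c(x, y) um (spheroid centre from frame 0).
#' @param sigma0 initial spheroid size, um.
#' @param k distance multiplier; a component is "dissociated" beyond
#'   `k * sigma0` (default 3).
#' @param cell_radius nominal cell spot scale, um; sets the default area
#'   bounds.
#' @param area_bounds c(min, max) component area in um^2 accepted as a single
#'   cell; defaults span a faint-threshold Gaussian spot of scale
#'   `cell_radius` while rejecting specks and merged pairs.
#' @details The threshold is Otsu's, computed on the log-compressed
#'   background-subtracted intensities: the spheroid core is orders of
#'   magnitude brighter than a detached single cell, and on a linear scale
#'   Otsu splits dim cells from the core instead of signal from background.
#' @return integer count, with attribute `components` (data frame of all
#'   components: x, y, area, distance, accepted).
#' @export
count_dissociated_singles <- function(frame, pixel_size, center, sigma0,
                                      k = 3, cell_radius = 4,
                                      area_bounds = c(0.5, 15) * pi * cell_radius^2) {
  img <- subtract_background(frame)
  thr <- otsu_threshold(log1p(img))
  mask <- log1p(img) > thr
  if (!any(mask)) {
    warning("empty segmentation; count 0")
    return(structure(0L, components = data.frame()))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  n <- max(labm)
  idx <- which(labm > 0)
  rows <- (idx - 1L) %% nrow(labm) + 1L
  cols <- (idx - 1L) %/% nrow(labm) + 1L
  lv <- labm[idx]
  area_px <- tabulate(lv, n)
  cx <- tapply((cols - 1L) * pixel_size, lv, mean)
  cy <- tapply((rows - 1L) * pixel_size, lv, mean)
  comp <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                     area = area_px * pixel_size^2)
  comp$distance <- sqrt((comp$x - center[1L])^2 + (comp$y - center[2L])^2)
  comp$accepted <- comp$distance > k * sigma0 &
    comp$area >= area_bounds[1L] & comp$area <= area_bounds[2L]
  structure(sum(comp$accepted), components = comp)
}
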