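#' Calibrated multi-frame, multi-channel image series
#'
#' The pipeline's image container. Pixels are stored as a 4-d array
#' `[row, col, frame, channel]` of non-negative integer photon counts
#' (0..65535, the 16-bit camera range). Physical calibration is mandatory:
#' all downstream computation is carried out in micrometres and minutes, and
#' conversion from pixels/frames happens only here. Coordinates follow the
#' image convention: pixel (0,0) is the top-left pixel centre, x runs along
#' columns (`x = col * pixel_size` with 0-based columns) and y along rows.
#'
#' @param pixels numeric array `[row, col, frame, channel]` (a matrix or 3-d
#'   array is promoted, assuming single frame and/or single channel).
#' @param pixel_size um/pixel (> 0).
#' @param frame_interval minutes between frames (> 0).
#' @param channel_names character vector naming the channels, e.g.
#'   `c(green = "MDA-MB-231-EGFP", red = "MCF-10A-dTomato")`.
#' @return object of class `image_series`.
#' @export
image_series <- function(pixels, pixel_size, frame_interval,
                         channel_names = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 4L) stop("pixels must have 2-4 dimensions")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  nc <- dim(pixels)[4L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length must equal the number of channels")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_names = as.character(channel_names)),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(paste0("<image_series> %d x %d px, %d frame(s), %d channel(s)\n",
                     "  pixel size %.4g um/px, frame interval %.4g min",
                     " (total %.1f h)\n  channels: %s\n"),
              d[1], d[2], d[3], d[4], x$pixel_size, x$frame_interval,
              (d[3] - 1) * x$frame_interval / 60,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Total duration of an image series in hours
#'
#' `(n_frames - 1) * frame_interval`, i.e. the time spanned from the first to
#' the last frame.
#' @param series an [image_series()].
#' @export
series_duration_hours <- function(series) {
  (dim(series$pixels)[3L] - 1L) * series$frame_interval / 60
}

#' Extract a single frame of one channel as a matrix
#'
#' @param series an [image_series()].
#' @param frame_index 0-based frame index.
#' @param channel channel index or name.
#' @export
series_frame <- function(series, frame_index, channel = 1L) {
  get_frame(series, frame_index, channel)
}

# extract frame as matrix
get_frame <- function(series, frame_index, channel = 1L) {
  ch <- resolve_channel(series, channel)
  series$pixels[, , frame_index + 1L, ch, drop = TRUE]
}

resolve_channel <- function(series, channel) {
  if (is.character(channel)) {
    ch <- match(channel, series$channel_names)
    if (is.na(ch)) stop("unknown channel '", channel, "'")
    ch
  } else as.integer(channel)
}

#' Write an image series to multi-page TIFF plus a manifest
#'
#' One 16-bit multi-page TIFF per channel (frame-major pages), named
#' `<basename>_<channel>.tif`, plus a YAML manifest `<basename>_manifest.yml`
#' recording the calibration (pixel size, frame interval), channel names and
#' the coordinate convention. Pixel values must be integers in 0..65535;
#' writing is lossless for such data.
#'
#' @param series an [image_series()].
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return the manifest path, invisibly.
#' @export
write_image_series <- function(series, dir, basename = "series") {
  px <- series$pixels
  if (any(px != round(px)) || max(px) > 65535)
    stop("pixels must be integer counts in 0..65535 for 16-bit TIFF output")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(px)
  files <- character(d[4L])
  for (ch in seq_len(d[4L])) {
    pages <- lapply(seq_len(d[3L]), function(fr) px[, , fr, ch] / 65535)
    files[ch] <- file.path(dir, sprintf("%s_%s.tif", basename,
                                        series$channel_names[ch]))
    tiff::writeTIFF(pages, files[ch], bits.per.sample = 16L)
  }
  manifest <- list(
    format = "spheroquant-image-series", version = 1L,
    pixel_size_um = series$pixel_size,
    frame_interval_min = series$frame_interval,
    n_frames = d[3L], image_shape = d[1:2],
    channel_names = as.list(series$channel_names),
    channel_files = as.list(basename(files)),
    coordinates = "0-based pixel-center; x along columns, y along rows",
    intensity = "16-bit integer counts")
  mpath <- file.path(dir, paste0(basename, "_manifest.yml"))
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read an image series written by [write_image_series()]
#'
#' @param path the `*_manifest.yml` path (or a directory containing exactly
#'   one manifest).
#' @param pixel_size,frame_interval optional calibration overrides; required
#'   if the manifest lacks them. Physical units are never guessed.
#' @return an [image_series()], bit-identical to what was written.
#' @export
read_image_series <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (dir.exists(path)) {
    m <- list.files(path, pattern = "_manifest\\.yml$", full.names = TRUE)
    if (length(m) != 1L) stop("expected exactly one *_manifest.yml in ", path)
    path <- m
  }
  man <- yaml::read_yaml(path)
  ps <- pixel_size %||% man$pixel_size_um
  fi <- frame_interval %||% man$frame_interval_min
  if (is.null(ps) || is.null(fi))
    stop("calibration (pixel_size, frame_interval) missing from manifest and not supplied")
  dir <- dirname(path)
  chans <- unlist(man$channel_names)
  arrs <- lapply(unlist(man$channel_files), function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    shp <- dim(pages[[1L]])
    if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
      stop("mismatched frame shapes in ", f)
    arr <- array(0, c(shp, length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * 65535)
    arr
  })
  shp <- dim(arrs[[1L]])
  if (!all(vapply(arrs, function(a) identical(dim(a), shp), logical(1))))
    stop("mismatched frame shapes across channels")
  px <- array(0, c(shp, length(arrs)))
  for (ch in seq_along(arrs)) px[, , , ch] <- arrs[[ch]]
  image_series(px, ps, fi, chans)
}
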