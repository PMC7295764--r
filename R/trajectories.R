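#' Per-cell trajectory table
#'
#' A validated data frame of tracked positions with columns `cell_id`,
#' `frame` (0-based index), `x`, `y` (micrometres), carrying the frame
#' interval (minutes) and an optional condition label (`"control"`, `"flow"`)
#' as attributes. `(cell_id, frame)` pairs must be unique and frames strictly
#' increasing within each cell; gaps are allowed but flagged.
#'
#' @param df data frame with columns cell_id, frame, x, y.
#' @param frame_interval minutes between consecutive frame indices.
#' @param condition optional condition label.
#' @return object of class `trajectory_set` (a data.frame).
#' @export
trajectory_set <- function(df, frame_interval, condition = NA_character_) {
  req <- c("cell_id", "frame", "x", "y")
  if (!all(req %in% names(df))) {
    stop("trajectory table needs columns: ", paste(req, collapse = ", "))
  }
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  df <- as.data.frame(df)[req]
  df$frame <- as.integer(df$frame)
  if (anyDuplicated(df[c("cell_id", "frame")])) {
    stop("duplicate (cell_id, frame) records")
  }
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  gaps <- vapply(split(df$frame, df$cell_id), function(f) {
    if (any(diff(f) <= 0)) stop("frames must be strictly increasing per cell")
    any(diff(f) > 1L)
  }, logical(1))
  structure(df, frame_interval = frame_interval,
            condition = condition, has_gaps = unname(gaps),
            class = c("trajectory_set", "data.frame"))
}

frame_interval_of <- function(ts) attr(ts, "frame_interval")

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d cells, %d records, dt = %g min%s\n",
              length(unique(x$cell_id)), nrow(x), attr(x, "frame_interval"),
              if (!is.na(attr(x, "condition")))
                paste0(", condition = ", attr(x, "condition")) else ""))
  if (any(attr(x, "has_gaps"))) {
    cat(sprintf("  %d track(s) contain frame gaps\n", sum(attr(x, "has_gaps"))))
  }
  invisible(x)
}

#' Rose plot of trajectories
#'
#' All tracks re-origined to (0, 0), the standard way migration trajectories
#' are displayed.
#' @param x a [trajectory_set()].
#' @param col line colour.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_set <- function(x, col = grDevices::adjustcolor("steelblue", 0.6), ...) {
  sp <- split(x[c("x", "y")], x$cell_id)
  re <- lapply(sp, function(d) data.frame(x = d$x - d$x[1L], y = d$y - d$y[1L]))
  lim <- max(abs(unlist(re)), 1)
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  for (d in re) graphics::lines(d$x, d$y, col = col)
  invisible(x)
}

#' Read / write trajectory tables
#'
#' Comma-separated text with mandatory header `cell_id,frame,x,y`; positions
#' in micrometres. Coordinates are written at full double precision so a
#' write/read round trip is lossless.
#'
#' @param path file path.
#' @param frame_interval minutes between frames (not stored in the file).
#' @param condition optional condition label.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path, frame_interval, condition = NA_character_) {
  df <- utils::read.csv(path, colClasses = c(NA, "integer", "numeric", "numeric"))
  req <- c("cell_id", "frame", "x", "y")
  if (!identical(names(df)[seq_len(4L)], req)) {
    stop("expected header: ", paste(req, collapse = ","))
  }
  trajectory_set(df, frame_interval, condition)
}

#' @rdname read_trajectories
#' @param ts a [trajectory_set()].
#' @export
write_trajectories <- function(ts, path) {
  out <- data.frame(cell_id = ts$cell_id, frame = ts$frame,
                    x = sprintf("%.17g", ts$x), y = sprintf("%.17g", ts$y))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
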