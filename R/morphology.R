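# Cell-shape quantification: segmentation, moment-equivalent ellipse fit,
# amoeboid vs mesenchymal classification by aspect ratio.

#' Segment sparse single cells
#'
#' Background subtraction (median of the darkest 5% of pixels), Otsu
#' threshold, connected-component labelling, then an area filter. Touching
#' cells merge into one oversize component and are excluded by the upper
#' area bound rather than split.
#'
#' @param image intensity matrix.
#' @param pixel_size um/pixel.
#' @param min_area,max_area accepted component area, um^2.
#' @return list with `labels` (integer matrix, 0 = background, accepted
#'   components relabelled 1..n), `n_cells`, and `n_rejected` (components
#'   outside the area bounds).
#' @export
segment_cells <- function(image, pixel_size, min_area = 20, max_area = 2000) {
  img <- subtract_background(image)
  thr <- otsu_threshold(img)
  mask <- img > thr
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(image), ncol(image)),
                n_cells = 0L, n_rejected = 0L))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  areas <- tabulate(lab[lab > 0], n) * pixel_size^2
  keep <- which(areas >= min_area & areas <= max_area)
  relab <- integer(n)
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  list(labels = out, n_cells = length(keep), n_rejected = n - length(keep))
}

#' Moment-equivalent ellipse and aspect ratio of one mask
#'
#' Computes the ellipse with the same area and second central moments as the
#' pixel mask (the ImageJ "Fit Ellipse" convention): the eigenvalues
#' `l1 >= l2` of the coordinate covariance give semi-axes `2 sqrt(l)`, and
#' the aspect ratio is `major / minor = sqrt(l1 / l2)`.
#'
#' @param mask logical or 0/1 matrix with a single cell.
#' @param pixel_size um/pixel.
#' @param cell_id identifier carried into the record.
#' @param threshold aspect ratio at and above which a cell is classified
#'   mesenchymal (elongated); below it, amoeboid (rounded). Default 2.
#' @return one-row data frame (class `shape_record`): cell_id, major_axis,
#'   minor_axis (full axes, um), aspect_ratio, mode.
#' @export
ellipse_aspect_ratio <- function(mask, pixel_size = 1, cell_id = 1L,
                                 threshold = 2) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  x <- (idx[, 2L] - 1L) * pixel_size
  y <- (idx[, 1L] - 1L) * pixel_size
  cxx <- mean((x - mean(x))^2); cyy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= .Machine$double.eps * max(l1, 1)) {
    stop("degenerate (collinear) mask: no ellipse fit")
  }
  ar <- sqrt(l1 / l2)
  structure(data.frame(cell_id = cell_id, major_axis = 4 * sqrt(l1),
                       minor_axis = 4 * sqrt(l2), aspect_ratio = ar,
                       mode = if (ar >= threshold) "mesenchymal" else "amoeboid"),
            class = c("shape_record", "data.frame"))
}

#' Shape records for every segmented cell in an image
#'
#' Convenience wrapper: [segment_cells()] then [ellipse_aspect_ratio()] per
#' component. Degenerate components are skipped with a message.
#'
#' @inheritParams segment_cells
#' @inheritParams ellipse_aspect_ratio
#' @return data frame of shape records (possibly 0 rows).
#' @export
shape_records <- function(image, pixel_size, min_area = 20, max_area = 2000,
                          threshold = 2) {
  seg <- segment_cells(image, pixel_size, min_area, max_area)
  recs <- list()
  for (i in seq_len(seg$n_cells)) {
    recs[[i]] <- tryCatch(
      ellipse_aspect_ratio(seg$labels == i, pixel_size, cell_id = i,
                           threshold = threshold),
      error = function(e) { message("cell ", i, " skipped: ", conditionMessage(e)); NULL })
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(), major_axis = numeric(),
                      minor_axis = numeric(), aspect_ratio = numeric(),
                      mode = character())
  }
  out
}

#' Population-level morphology summary
#'
#' Fraction of mesenchymal cells (aspect ratio at or above the threshold,
#' inclusive) with its binomial standard error, and the aspect-ratio
#' histogram.
#'
#' @param records data frame with an `aspect_ratio` column (e.g. from
#'   [shape_records()]).
#' @param threshold mesenchymal classification threshold (default 2).
#' @param bin_width histogram bin width (default 0.25).
#' @return object of class `morphology_summary`: list with `n`,
#'   `fraction_mesenchymal`, `se` (binomial), `threshold`, `histogram`
#'   (data frame mid, count, density).
#' @export
classify_population <- function(records, threshold = 2, bin_width = 0.25) {
  ar <- records$aspect_ratio
  if (length(ar) < 1L) stop("need at least one shape record")
  p <- mean(ar >= threshold)
  breaks <- seq(1, max(ar, threshold) + bin_width, by = bin_width)
  h <- graphics::hist(ar, breaks = breaks, plot = FALSE)
  structure(list(n = length(ar), fraction_mesenchymal = p,
                 se = sqrt(p * (1 - p) / length(ar)), threshold = threshold,
                 histogram = data.frame(mid = h$mids, count = h$counts,
                                        density = h$density)),
            class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  cat(sprintf("<morphology_summary> n = %d cells: %.1f%% mesenchymal (AR >= %g), SE %.1f%%\n",
              x$n, 100 * x$fraction_mesenchymal, x$threshold, 100 * x$se))
  invisible(x)
}

#' @export
plot.morphology_summary <- function(x, ...) {
  graphics::barplot(x$histogram$count, names.arg = x$histogram$mid,
                    xlab = "aspect ratio", ylab = "cells", ...)
  graphics::abline(v = NULL)
  invisible(x)
}
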