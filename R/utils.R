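# Internal helpers shared across stages.

#' Estimate the image background level
#'
#' Two estimators are provided: `"dark_median"`, the median of the darkest
#' fraction of pixels (default 5%), robust for sparse fluorescence images where
#' most pixels are background; and `"mode"`, the most frequent intensity value,
#' appropriate for sum projections where the background dominates the
#' histogram.
#'
#' @param img numeric matrix of intensities.
#' @param method `"dark_median"` or `"mode"`.
#' @param dark_fraction fraction of darkest pixels used by `"dark_median"`.
#' @return scalar background level, in the intensity units of `img`.
#' @export
background_level <- function(img, method = c("dark_median", "mode"),
                             dark_fraction = 0.05) {
  method <- match.arg(method)
  v <- as.numeric(img)
  if (length(v) == 0L || !all(is.finite(v))) {
    stop("image must be non-empty with finite intensities")
  }
  if (method == "dark_median") {
    k <- max(1L, floor(length(v) * dark_fraction))
    stats::median(sort(v, partial = k)[seq_len(k)])
  } else {
    # histogram mode; integer-count images get exact value counts
    if (all(v == round(v))) {
      tab <- tabulate(as.integer(v - min(v)) + 1L)
      (which.max(tab) - 1L) + min(v)
    } else {
      h <- graphics::hist(v, breaks = 256L, plot = FALSE)
      h$mids[which.max(h$counts)]
    }
  }
}

# subtract background and clip at zero
subtract_background <- function(img, method = "dark_median", ...) {
  pmax(img - background_level(img, method = method, ...), 0)
}

# Otsu threshold on a background-subtracted image; EBImage expects [0, 1]
otsu_threshold <- function(img) {
  mx <- max(img)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
}

stopifnot_scalar <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (integer && x != round(x)) stop(sprintf("'%s' must be an integer", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
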