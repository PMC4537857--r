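#' Binarize a raw root-core image
#'
#' Converts a raw grayscale or RGB image to a binary silhouette: luminance
#' grayscale conversion, optional background-frame subtraction (absolute
#' difference), then a global threshold. A pixel is foreground iff its
#' value is strictly greater than the threshold, so a pixel exactly at the
#' threshold is background.
#'
#' @param raw Numeric matrix (grayscale) or `H x W x 3` array (RGB),
#'   intensities in \[0, 1\] as returned by [png::readPNG()].
#' @param threshold Global threshold in \[0, 1\]; strictly-greater pixels
#'   become foreground.
#' @param background Optional background reference frame of the same
#'   geometry; when given, the absolute difference from it is thresholded
#'   instead of the image itself.
#' @return A [binary_image()].
#' @export
preprocess <- function(raw, threshold = 0.5, background = NULL) {
  if (length(raw) == 0L) stop("empty image")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  gray <- to_luminance(raw)
  if (!is.null(background)) {
    bg <- to_luminance(background)
    if (!identical(dim(bg), dim(gray))) {
      stop("background frame geometry does not match the image")
    }
    gray <- abs(gray - bg)
  }
  mask <- gray > threshold
  if (!any(mask)) stop("empty silhouette: no foreground after thresholding")
  binary_image(mask)
}

# Rec. 601 luminance for RGB; pass-through for grayscale.
to_luminance <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    if (d[3L] >= 3L) {
      0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x[, , 1L]
    }
  } else if (length(d) == 2L) {
    x
  } else {
    stop("raw image must be a matrix or H x W x channels array")
  }
}
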