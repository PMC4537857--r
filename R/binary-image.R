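#' Binary root silhouette images
#'
#' A `binary_image` is a logical matrix (rows = image rows, top row first;
#' columns = image columns, left first) where `TRUE` marks foreground (root
#' tissue). It is the common currency between the synthetic renderer, the
#' preprocessing step and all trait measurements.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param meta Optional named list of metadata (e.g. the theoretical box
#'   dimension of a rendered fixture).
#' @return An object of class `binary_image`: the logical matrix with a
#'   `meta` attribute.
#' @examples
#' img <- binary_image(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' dim(img)
#' @export
binary_image <- function(mask, meta = list()) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(mask, meta = meta, class = c("binary_image", "matrix", "array"))
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d, %d foreground px (%.1f%%)>\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  meta:", paste(names(meta), unlist(lapply(meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

next_power_of_two <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' Pad a binary image with background to a square power-of-two canvas
#'
#' Box counting assumes a square canvas whose side every box size divides;
#' images are padded (bottom/right) with background to the next power of two.
#'
#' @param image A [binary_image()] or logical matrix.
#' @return A `binary_image` whose side is a power of two.
#' @export
pad_pow2 <- function(image) {
  side <- next_power_of_two(max(nrow(image), ncol(image)))
  if (nrow(image) == side && ncol(image) == side) {
    return(binary_image(unclass(image), attr(image, "meta") %||% list()))
  }
  out <- matrix(FALSE, side, side)
  out[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  binary_image(out, attr(image, "meta") %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG, foreground white (255),
#' background black (0). Reading applies a fixed mid-gray cut so that a
#' round trip is lossless.
#'
#' @param image A [binary_image()].
#' @param path File path.
#' @return `read_mask_png` returns a `binary_image`; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(image, path) {
  png::writePNG(ifelse(unclass(image), 1, 0), target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  binary_image(arr > 0.5)
}
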