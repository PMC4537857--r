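#' Box counting of a binary silhouette
#'
#' Tiles the image with grids of square boxes of side `L` (pixels), anchored
#' at the image origin, and counts the number of boxes `N_L` containing at
#' least one foreground pixel at each scale. Images whose side is not a
#' power of two are first padded with background to the next power of two.
#'
#' The default scale ladder is the ten powers of two 1, 2, 4, ..., 512,
#' spanning log10(512) ~ 2.7 orders of magnitude; scales exceeding the
#' (padded) canvas side are dropped.
#'
#' @param image A [binary_image()] or logical matrix with at least one
#'   foreground pixel.
#' @param box_sizes Integer vector of box sides; each must divide the
#'   padded canvas side. Default `2^(0:9)`.
#' @return A data frame of class `box_count_curve` with columns `L` (box
#'   side) and `N` (occupied boxes), ordered by increasing `L`.
#' @examples
#' img <- render_known_fractal("line", 64)
#' box_count(img, 2^(0:6))
#' @export
box_count <- function(image, box_sizes = 2L^(0:9)) {
  img <- pad_pow2(image)
  side <- nrow(img)
  if (!any(img)) stop("empty image: no foreground pixels to count")
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes <= side]
  if (length(box_sizes) == 0L) stop("no box size fits the canvas")
  if (any(box_sizes < 1L)) stop("box sizes must be positive")
  if (any(side %% box_sizes != 0L)) {
    stop("box sizes must divide the canvas side (", side, "): ",
         paste(box_sizes[side %% box_sizes != 0L], collapse = ", "))
  }
  fg <- which(unclass(img), arr.ind = TRUE)
  counts <- vapply(box_sizes, function(L) {
    cell_r <- (fg[, 1L] - 1L) %/% L
    cell_c <- (fg[, 2L] - 1L) %/% L
    length(unique(cell_r * (side %/% L) + cell_c))
  }, integer(1))
  structure(data.frame(L = box_sizes, N = counts),
            class = c("box_count_curve", "data.frame"))
}

#' Fit the box-count power law
#'
#' Estimates the fractal dimension and fractal abundance from a box-count
#' curve by ordinary least squares of `log(N_L)` on `log(L)` (natural
#' logarithms):
#'
#' \deqn{\log N_L = \log K - D \log L}
#'
#' The fractal dimension FD is minus the fitted slope (`D`); the fractal
#' abundance FA is the fitted intercept `log K` (so `K = exp(FA)`); a
#' single unbranched root gives FD = 1 and a space-filling silhouette
#' FD = 2 on the default ladder.
#'
#' @param curve A `box_count_curve` from [box_count()], or a data frame
#'   with columns `L` and `N`.
#' @return A list of class `fractal_estimate` with elements `FD`, `FA`
#'   (natural-log scale), `K` (`exp(FA)`), `fit_r2`, `local_dims`
#'   (see [local_dimensions()]), and `curve`.
#' @examples
#' fit_fractal(box_count(render_known_fractal("filled", 64), 2^(0:6)))$FD
#' @export
fit_fractal <- function(curve) {
  if (!all(c("L", "N") %in% names(curve))) {
    stop("curve must have columns L and N")
  }
  if (nrow(curve) < 3L) stop("need at least 3 scales to fit, got ",
                             nrow(curve))
  if (any(curve$N < 1)) stop("box counts must be >= 1")
  x <- log(curve$L)
  y <- log(curve$N)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2L]
  intercept <- fit$coefficients[1L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(FD = unname(-slope),
                 FA = unname(intercept),
                 K = unname(exp(intercept)),
                 fit_r2 = unname(r2),
                 local_dims = local_dimensions(curve),
                 curve = curve),
            class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate FD=%.4f FA=%.4f (K=%.4g) r2=%.4f, %d scales>\n",
              x$FD, x$FA, x$K, x$fit_r2, nrow(x$curve)))
  invisible(x)
}

#' Local box dimensions between consecutive scales
#'
#' The negated slope of `log N` vs `log L` between each pair of consecutive
#' scales; a diagnostic of where on the scale ladder the power law holds.
#' The default ten-size ladder yields nine local dimensions.
#'
#' @inheritParams fit_fractal
#' @return Numeric vector of length `nrow(curve) - 1`, named
#'   `"L1-L2"` per scale pair.
#' @export
local_dimensions <- function(curve) {
  if (nrow(curve) < 2L) stop("need at least 2 scales, got ", nrow(curve))
  x <- log(curve$L)
  y <- log(curve$N)
  n <- nrow(curve)
  d <- -diff(y) / diff(x)
  names(d) <- paste(curve$L[-n], curve$L[-1L], sep = "-")
  d
}
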