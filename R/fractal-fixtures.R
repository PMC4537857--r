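#' Render reference fractal fixtures of known box dimension
#'
#' Deterministic rasters whose box-counting dimension is known analytically,
#' used to validate the fractal estimation machinery. Three kinds are
#' available:
#'
#' * `"line"` — a single full-width one-pixel horizontal row: the silhouette
#'   of a single unbranched root; theoretical dimension 1.
#' * `"filled"` — every pixel foreground: the space-filling limit of a
#'   highly branched system; theoretical dimension 2.
#' * `"sierpinski_triangle"` — the discrete Sierpinski gasket obtained by
#'   `level` rounds of quadrant subdivision, dropping the upper-right
#'   quadrant each round; theoretical dimension log(3)/log(2) ~ 1.585.
#'
#' @param kind One of `"line"`, `"filled"`, `"sierpinski_triangle"`.
#' @param canvas_size_px Square canvas side in pixels; must be a power of
#'   two so the full power-of-two box ladder applies.
#' @param level Subdivision depth for the Sierpinski gasket; must satisfy
#'   `2^level <= canvas_size_px`. Ignored for the other kinds.
#' @return A [binary_image()] with metadata fields `kind`, `level`, and
#'   `theoretical_dim`.
#' @examples
#' img <- render_known_fractal("sierpinski_triangle", 64, level = 6)
#' attr(img, "meta")$theoretical_dim
#' @export
render_known_fractal <- function(kind = c("line", "filled",
                                          "sierpinski_triangle"),
                                 canvas_size_px = 512L, level = NULL) {
  kind <- match.arg(kind)
  side <- as.integer(canvas_size_px)
  if (!is_power_of_two(side)) {
    stop("canvas_size_px must be a power of two, got ", canvas_size_px)
  }
  max_level <- as.integer(round(log2(side)))
  mask <- switch(kind,
    filled = matrix(TRUE, side, side),
    line = {
      m <- matrix(FALSE, side, side)
      m[side %/% 2L, ] <- TRUE   # one full-width 1-px row
      m
    },
    sierpinski_triangle = {
      if (is.null(level)) level <- max_level
      level <- as.integer(level)
      if (level < 0L || 2L^level > side) {
        stop("level ", level, " too deep for a ", side, "-px canvas")
      }
      # cell (i, j) survives `level` rounds of subdivision iff the top
      # `level` bits of its coordinates never select the dropped quadrant:
      # bitwAnd(row, col) == 0 on the level-bit prefix (Pascal mod 2).
      cell <- side %/% 2L^level
      idx <- 0L:(2L^level - 1L)
      keep <- outer(idx, idx, function(r, co) bitwAnd(r, co) == 0L)
      m <- keep[rep(seq_len(2L^level), each = cell),
                rep(seq_len(2L^level), each = cell)]
      m
    })
  theo <- switch(kind,
    filled = 2,
    line = 1,
    sierpinski_triangle = log(3) / log(2))
  binary_image(mask, meta = list(kind = kind,
                                 level = if (kind == "sierpinski_triangle")
                                   level else NA_integer_,
                                 theoretical_dim = theo))
}

#' Write a set of fractal fixtures with a manifest
#'
#' Renders one fixture per row of `specs`, writes each as a PNG and returns
#' (and writes) a manifest CSV with columns `path`, `kind`, `level`,
#' `theoretical_dim`, `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param specs Data frame with columns `kind`, `canvas_size_px`, `level`.
#'   Defaults to the three standard fixtures on a 512-px canvas.
#' @param seed Integer recorded in the manifest (the fixtures themselves
#'   are deterministic).
#' @return The manifest data frame, invisibly; written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_fractal_fixtures <- function(dir,
                                   specs = data.frame(
                                     kind = c("line", "filled",
                                              "sierpinski_triangle"),
                                     canvas_size_px = 512L,
                                     level = c(NA, NA, 9L)),
                                   seed = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    kind <- specs$kind[i]
    lev <- specs$level[i]
    img <- render_known_fractal(kind, specs$canvas_size_px[i],
                                level = if (is.na(lev)) NULL else lev)
    path <- file.path(dir, sprintf("%s_%d.png", kind, specs$canvas_size_px[i]))
    write_mask_png(img, path)
    data.frame(path = path, kind = kind,
               level = if (is.na(lev)) NA_integer_ else as.integer(lev),
               theoretical_dim = attr(img, "meta")$theoretical_dim,
               seed = as.integer(seed))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
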