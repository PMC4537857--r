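#' Parameters for the stochastic branching root-system generator
#'
#' Describes a maize-like root core: a vertical stem, whorls of shoot-borne
#' (brace/crown) roots emitted from compact nodes near the stem base, and
#' recursive lateral branching. The generator is a simple stochastic
#' recursive branching process, not a biomechanical model: only the
#' silhouette statistics matter downstream.
#'
#' @param stem_diameter_px Stem width in pixels (> 0); default 8% of the
#'   canvas side.
#' @param cone_half_angle_deg Half-angle of the root cone in degrees,
#'   in (0, 90); initial shoot-borne root directions deviate at most this
#'   far from the downward vertical.
#' @param n_nodes Number of whorls of shoot-borne roots (maize forms about
#'   six compact underground nodes).
#' @param roots_per_node Shoot-borne roots per whorl.
#' @param branch_prob Probability, per candidate site per segment, that a
#'   lateral of the next order emerges; in \[0, 1\].
#' @param max_order Maximum lateral order; order-`max_order` segments never
#'   branch (0 = no laterals at all).
#' @param segment_length_px Length of a shoot-borne root segment, pixels;
#'   default 35% of the canvas side.
#' @param length_decay Multiplicative length decay per lateral order,
#'   in (0, 1\].
#' @param lateral_sites Candidate lateral insertion points per segment.
#' @param rng_seed Integer seed; all randomness in [grow_root_system()]
#'   flows through it.
#' @param canvas_size_px Square canvas side for later projection.
#' @return A validated list of class `growth_params`.
#' @export
growth_params <- function(stem_diameter_px = NULL,
                          cone_half_angle_deg = 35,
                          n_nodes = 6L,
                          roots_per_node = 8L,
                          branch_prob = 0.5,
                          max_order = 2L,
                          segment_length_px = NULL,
                          length_decay = 0.45,
                          lateral_sites = 4L,
                          rng_seed = 1L,
                          canvas_size_px = 512L) {
  if (is.null(stem_diameter_px)) stem_diameter_px <- 0.08 * canvas_size_px
  if (is.null(segment_length_px)) segment_length_px <- 0.35 * canvas_size_px
  p <- list(stem_diameter_px = stem_diameter_px,
            cone_half_angle_deg = cone_half_angle_deg,
            n_nodes = as.integer(n_nodes),
            roots_per_node = as.integer(roots_per_node),
            branch_prob = branch_prob,
            max_order = as.integer(max_order),
            segment_length_px = segment_length_px,
            length_decay = length_decay,
            lateral_sites = as.integer(lateral_sites),
            rng_seed = as.integer(rng_seed),
            canvas_size_px = as.integer(canvas_size_px))
  stopifnot(p$stem_diameter_px > 0,
            p$cone_half_angle_deg > 0, p$cone_half_angle_deg < 90,
            p$n_nodes >= 1L, p$roots_per_node >= 1L,
            p$branch_prob >= 0, p$branch_prob <= 1,
            p$max_order >= 0L,
            p$segment_length_px > 0, p$length_decay > 0,
            p$length_decay <= 1, p$lateral_sites >= 1L,
            p$canvas_size_px >= 16L)
  class(p) <- "growth_params"
  p
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Random unit vector within `half_angle` (radians) of direction `axis`.
# Polar deviation defaults to uniform on [0, half_angle]; callers may pass
# their own draw (still capped at half_angle).
random_cone_dir <- function(axis, half_angle, azimuth = NULL, polar = NULL) {
  theta <- if (is.null(polar)) stats::runif(1, 0, half_angle) else
    min(polar, half_angle)
  phi <- if (is.null(azimuth)) stats::runif(1, 0, 2 * pi) else azimuth
  # orthonormal frame around axis
  a <- unit3(axis)
  ref <- if (abs(a[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit3(pracma_cross(a, ref))
  v <- pracma_cross(a, u)
  cos(theta) * a + sin(theta) * (cos(phi) * u + sin(phi) * v)
}

pracma_cross <- function(x, y) {
  c(x[2L] * y[3L] - x[3L] * y[2L],
    x[3L] * y[1L] - x[1L] * y[3L],
    x[1L] * y[2L] - x[2L] * y[1L])
}

#' Grow a synthetic root system
#'
#' Generates a 3-D segment model of a root core from [growth_params()]:
#' one vertical stem at the canvas centre, `n_nodes * roots_per_node`
#' shoot-borne roots whose initial directions lie within the root cone,
#' and recursive laterals. Each root or lateral is a single straight
#' capsule segment; laterals of order `o + 1` emerge from candidate sites
#' along an order-`o` segment with probability `branch_prob`, with length
#' scaled by `length_decay` per order. The process is seed-reproducible
#' and uses no global RNG state.
#'
#' Coordinates: x, y horizontal (canvas centred), z depth (0 at canvas
#' top, increasing downward).
#'
#' @param params A [growth_params()] object.
#' @return A list of class `root_system_model` with elements `segments`
#'   (data frame: `x0,y0,z0,x1,y1,z1,radius,order_tag`) and
#'   `canvas_size_px`.
#' @examples
#' m <- grow_root_system(growth_params(branch_prob = 0, n_nodes = 3,
#'                                     roots_per_node = 4))
#' nrow(m$segments)  # stem + 12 unbranched roots
#' @export
grow_root_system <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(params$rng_seed)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    grow_root_system_impl(params)
  })
  rng
}

grow_root_system_impl <- function(p) {
  side <- p$canvas_size_px
  cx <- side / 2
  stem_top <- 0
  node_zone_top <- side * 0.13
  node_zone_bot <- side * 0.18
  stem_len <- node_zone_bot
  segs <- list(data.frame(x0 = cx, y0 = cx, z0 = stem_top,
                          x1 = cx, y1 = cx, z1 = stem_len,
                          radius = p$stem_diameter_px / 2,
                          order_tag = "stem"))
  half <- p$cone_half_angle_deg * pi / 180
  node_z <- seq(node_zone_top, node_zone_bot, length.out = p$n_nodes)
  root_radius <- max(1, p$stem_diameter_px / 8)
  queue <- list()
  for (nz in node_z) {
    base_phi <- stats::runif(1, 0, 2 * pi)
    for (r in seq_len(p$roots_per_node)) {
      phi <- base_phi + 2 * pi * (r - 1) / p$roots_per_node +
        stats::rnorm(1, 0, 0.1)
      # whorl roots define the cone: they emerge essentially at the cone
      # surface, with a small inward Beta-distributed jitter
      theta <- half * stats::rbeta(1, 40, 1.2)
      dir <- random_cone_dir(c(0, 0, 1), half, azimuth = phi, polar = theta)
      start <- c(cx, cx, nz)
      end <- start + dir * p$segment_length_px
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = start[1L], y0 = start[2L], z0 = start[3L],
        x1 = end[1L], y1 = end[2L], z1 = end[3L],
        radius = root_radius, order_tag = "shoot_borne")
      if (p$max_order >= 1L) {
        queue[[length(queue) + 1L]] <- list(start = start, end = end,
                                            order = 1L)
      }
    }
  }
  # breadth-first lateral branching
  while (length(queue) > 0L) {
    item <- queue[[1L]]
    queue <- queue[-1L]
    parent_dir <- unit3(item$end - item$start)
    len <- p$segment_length_px * p$length_decay^item$order
    rad <- max(0.6, root_radius * 0.6^item$order)
    for (s in seq_len(p$lateral_sites)) {
      if (stats::runif(1) >= p$branch_prob) next
      t_pos <- stats::runif(1, 0.15, 0.95)
      start <- item$start + t_pos * (item$end - item$start)
      dir <- random_cone_dir(parent_dir, 70 * pi / 180)
      if (dir[3L] < 0) dir[3L] <- -dir[3L] * 0.3  # bias downward
      dir <- unit3(dir)
      end <- start + dir * len
      # roots grow downward-outward but stay inside the root cone; clamp
      # endpoints radially onto the cone surface (apex at the top node)
      end <- clamp_to_cone(end, cx, node_zone_top, half)
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = start[1L], y0 = start[2L], z0 = start[3L],
        x1 = end[1L], y1 = end[2L], z1 = end[3L],
        radius = rad, order_tag = "lateral")
      if (item$order < p$max_order) {
        queue[[length(queue) + 1L]] <- list(start = start, end = end,
                                            order = item$order + 1L)
      }
    }
  }
  structure(list(segments = do.call(rbind, segs),
                 canvas_size_px = side,
                 params = p),
            class = "root_system_model")
}

clamp_to_cone <- function(pt, cx, apex_z, half) {
  dz <- pt[3L] - apex_z
  max_r <- if (dz > 0) dz * tan(half) else 0
  r <- sqrt((pt[1L] - cx)^2 + (pt[2L] - cx)^2)
  if (r > max_r) {
    sc <- if (r > 0) max_r / r else 0
    pt[1L] <- cx + (pt[1L] - cx) * sc
    pt[2L] <- cx + (pt[2L] - cx) * sc
  }
  pt
}

#' @export
print.root_system_model <- function(x, ...) {
  cat(sprintf("<root_system_model: %d segments (%s) on %d-px canvas>\n",
              nrow(x$segments),
              paste(names(table(x$segments$order_tag)),
                    table(x$segments$order_tag), sep = ":", collapse = ", "),
              x$canvas_size_px))
  invisible(x)
}

#' Rotate a root system about the vertical stem axis
#'
#' @param model A `root_system_model`.
#' @param angle_deg Rotation angle, degrees, counter-clockwise viewed from
#'   above.
#' @return The rotated model.
#' @export
rotate_model <- function(model, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- model$canvas_size_px / 2
  s <- model$segments
  rot <- function(x, y) {
    list(x = cx + cos(th) * (x - cx) - sin(th) * (y - cx),
         y = cx + sin(th) * (x - cx) + cos(th) * (y - cx))
  }
  a <- rot(s$x0, s$y0); b <- rot(s$x1, s$y1)
  s$x0 <- a$x; s$y0 <- a$y; s$x1 <- b$x; s$y1 <- b$y
  model$segments <- s
  model
}

# Rasterize 2-D capsule segments (endpoints in continuous pixel coords,
# origin at top-left pixel corner) onto a side x side logical canvas.
# A pixel is foreground iff its centre lies within distance `radius` of
# the segment: no anti-aliasing, integer-reproducible.
rasterize_segments <- function(px0, py0, px1, py1, radius, side) {
  mask <- matrix(FALSE, side, side)   # rows = y (down), cols = x (right)
  for (i in seq_along(px0)) {
    r <- radius[i]
    xmin <- max(1L, floor(min(px0[i], px1[i]) - r) + 1L)
    xmax <- min(side, ceiling(max(px0[i], px1[i]) + r))
    ymin <- max(1L, floor(min(py0[i], py1[i]) - r) + 1L)
    ymax <- min(side, ceiling(max(py0[i], py1[i]) + r))
    if (xmin > xmax || ymin > ymax) next
    xc <- (xmin:xmax) - 0.5
    yc <- (ymin:ymax) - 0.5
    dx <- px1[i] - px0[i]; dy <- py1[i] - py0[i]
    len2 <- dx * dx + dy * dy
    X <- matrix(xc, nrow = length(yc), ncol = length(xc), byrow = TRUE)
    Y <- matrix(yc, nrow = length(yc), ncol = length(xc))
    if (len2 == 0) {
      d2 <- (X - px0[i])^2 + (Y - py0[i])^2
    } else {
      t_par <- ((X - px0[i]) * dx + (Y - py0[i]) * dy) / len2
      t_par[t_par < 0] <- 0
      t_par[t_par > 1] <- 1
      d2 <- (X - (px0[i] + t_par * dx))^2 + (Y - (py0[i] + t_par * dy))^2
    }
    hit <- d2 <= r * r
    mask[ymin:ymax, xmin:xmax] <- mask[ymin:ymax, xmin:xmax] | hit
  }
  mask
}

#' Project a root-system model to the standard five views
#'
#' Orthographic projections matching the imaging protocol: four horizontal
#' side views differing by 90-degree rotations about the stem axis (tags
#' `"0"`, `"90"`, `"180"`, `"270"`) plus one underside view along the
#' vertical axis. Segments are drawn as capsules with their radius; all
#' rasters share the model's canvas size.
#'
#' @param model A `root_system_model`.
#' @return A list of class `view_set` with elements `side_views` (named
#'   list of four [binary_image()]s) and `underside` (one `binary_image`).
#' @export
project_views <- function(model) {
  stopifnot(inherits(model, "root_system_model"))
  if (nrow(model$segments) == 0L) stop("empty model: no segments")
  side <- model$canvas_size_px
  cx <- side / 2
  angles <- c("0" = 0, "90" = 90, "180" = 180, "270" = 270)
  side_views <- lapply(angles, function(a) {
    m <- rotate_model(model, a)$segments
    # side view: horizontal axis = x, vertical axis = z (depth downward)
    binary_image(rasterize_segments(m$x0, m$z0, m$x1, m$z1, m$radius, side))
  })
  underside <- binary_image(
    rasterize_segments(model$segments$x0, model$segments$y0,
                       model$segments$x1, model$segments$y1,
                       model$segments$radius, side))
  structure(list(side_views = side_views, underside = underside,
                 canvas_size_px = side),
            class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf("<view_set: 4 side views + underside, %d-px canvas>\n",
              x$canvas_size_px))
  invisible(x)
}
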