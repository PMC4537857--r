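# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; nothing is read from disk.

# A stem bar of width `stem_w` above a solid wedge whose edges make
# `half_deg` with the vertical: the analytically known root-cone image.
make_wedge <- function(half_deg, side = 256L, stem_w = 20L,
                       apex_row = 60L) {
  m <- matrix(FALSE, side, side)
  cx <- side / 2
  m[1:apex_row, (cx - stem_w / 2 + 1):(cx + stem_w / 2)] <- TRUE
  s <- tan(half_deg * pi / 180)
  for (r in (apex_row + 1):side) {
    h <- (r - apex_row) * s
    lo <- max(1, ceiling(cx - h))
    hi <- min(side, floor(cx + h))
    if (lo <= hi) m[r, lo:hi] <- TRUE
  }
  binary_image(m)
}

# Strip class/metadata so two masks compare on pixels and shape only.
mask_of <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}

# Evaluate expr under a temporary seed without clobbering the RNG stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force box counting: nested loops over the grid cells.
box_count_oracle <- function(mask, L) {
  side <- nrow(mask)
  n <- 0L
  for (i in seq(1L, side, by = L)) {
    for (j in seq(1L, side, by = L)) {
      if (any(mask[i:(i + L - 1L), j:(j + L - 1L)])) n <- n + 1L
    }
  }
  n
}

# Cached ensemble of synthetic root samples with per-view measurements;
# built once per test run (used by several correlation/monotonicity
# properties).
root_sample_ensemble <- local({
  cache <- NULL
  function(n = 50L) {
    if (!is.null(cache) && nrow(cache) >= n) return(cache[seq_len(n), ])
    rows <- lapply(seq_len(n), function(i) {
      half <- 20 + (i %% 5) * 6 + (i %% 3)          # 20..46 degrees
      prm <- growth_params(rng_seed = 1000L + i,
                           cone_half_angle_deg = half,
                           branch_prob = 0.3 + 0.4 * ((i %% 7) / 6),
                           canvas_size_px = 256L)
      views <- project_views(grow_root_system(prm))
      ras <- vapply(views$side_views, function(sv) {
        tryCatch(measure_root_angle(sv)$RA, error = function(e) NA_real_)
      }, numeric(1))
      fds <- vapply(views$side_views, function(sv) {
        fit_fractal(box_count(sv, 2L^(0:8)))$FD
      }, numeric(1))
      und <- fit_fractal(box_count(views$underside, 2L^(0:8)))
      data.frame(sample = i, half_angle = half,
                 branch_prob = prm$branch_prob,
                 ra_0 = ras[1L], ra_90 = ras[2L], ra_180 = ras[3L],
                 ra_270 = ras[4L], ra_mean = mean(ras, na.rm = TRUE),
                 fd_side_0 = fds[1L], fd_side_90 = fds[2L],
                 fd_under = und$FD, fa_under = und$FA)
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})
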