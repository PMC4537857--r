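#' Stalk diameter from a side-view silhouette
#'
#' The stalk portion of a side view is the contiguous band of rows at the
#' top of the silhouette before the root cone flares out. It is detected
#' from the per-row foreground width profile: the reference width is the
#' median width over the top `band_frac` of foreground rows, and the band
#' ends at the first row whose width exceeds `flare_factor` times that
#' reference. The stalk diameter SD is the mean width (pixels) over the
#' stalk band.
#'
#' @param side_view A [binary_image()] side view, stem at the top.
#' @param flare_factor Width multiple that ends the stalk band (default
#'   1.5).
#' @param band_frac Fraction of foreground rows used for the reference
#'   median width (default 0.05).
#' @return A list with `SD` (mean width, px), `stalk_rows` (row index
#'   range of the band).
#' @export
measure_stalk_diameter <- function(side_view, flare_factor = 1.5,
                                   band_frac = 0.05) {
  prof <- row_width_profile(side_view)
  fg_rows <- which(!is.na(prof))
  if (length(fg_rows) == 0L) stop("no stalk detected: image is empty")
  top_limit <- ceiling(nrow(side_view) * 0.10)
  if (fg_rows[1L] > top_limit) {
    stop("no stalk detected: no foreground in the top 10% of rows")
  }
  n_ref <- max(3L, ceiling(length(fg_rows) * band_frac))
  ref_rows <- fg_rows[seq_len(min(n_ref, length(fg_rows)))]
  ref_width <- stats::median(prof[ref_rows])
  # walk down contiguous foreground rows until the profile flares
  band <- integer(0)
  r <- fg_rows[1L]
  while (r <= nrow(side_view) && !is.na(prof[r]) &&
         prof[r] <= flare_factor * ref_width) {
    band <- c(band, r)
    r <- r + 1L
  }
  if (length(band) == 0L) stop("no stalk detected: flare at the first row")
  list(SD = mean(prof[band]), stalk_rows = range(band))
}

# Per-row foreground extent (max col - min col + 1); NA for empty rows.
row_width_profile <- function(image) {
  m <- unclass(image)
  apply(m, 1L, function(row) {
    w <- which(row)
    if (length(w) == 0L) NA_real_ else diff(range(w)) + 1
  })
}

#' Root angle from a side-view silhouette
#'
#' The root angle RA is the full apex angle of the root cone seen in a
#' side view. The root region is taken as the rows below the stalk band
#' (see [measure_stalk_diameter()]); straight envelope lines are fitted by
#' least squares through the per-row extreme (leftmost/rightmost)
#' foreground columns of that region, and RA is the angle between the two
#' lines in degrees.
#'
#' @inheritParams measure_stalk_diameter
#' @param robust If `TRUE`, use the 5th/95th percentile columns per row
#'   instead of the extremes (for noisy silhouettes). The per-row
#'   percentile is over the foreground columns of the row.
#' @return A list with `RA` (degrees, in (0, 180)), `left_slope` and
#'   `right_slope` (column change per row, fitted).
#' @export
measure_root_angle <- function(side_view, flare_factor = 1.5,
                               band_frac = 0.05, robust = FALSE) {
  stalk <- measure_stalk_diameter(side_view, flare_factor, band_frac)
  m <- unclass(side_view)
  first_root_row <- stalk$stalk_rows[2L] + 1L
  if (first_root_row > nrow(m)) {
    stop("no root cone detected: root region empty below the stalk")
  }
  rows <- seq(first_root_row, nrow(m))
  edges <- lapply(rows, function(r) {
    w <- which(m[r, ])
    if (length(w) == 0L) return(NULL)
    if (robust) {
      q <- stats::quantile(w, c(0.05, 0.95), names = FALSE, type = 1L)
      data.frame(row = r, left = q[1L], right = q[2L])
    } else {
      data.frame(row = r, left = min(w), right = max(w))
    }
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) < 3L) {
    stop("no root cone detected: root region empty below the stalk")
  }
  # the cone is the widening upper part of the root region: fit the
  # envelopes from the cone top down to where the silhouette first
  # reaches (nearly) its maximum width — below the tips of the outermost
  # roots the profile plateaus or narrows and no longer carries the cone
  width <- edges$right - edges$left
  cone_end <- which(width >= 0.9 * max(width))[1L]
  if (cone_end >= 3L) edges <- edges[seq_len(cone_end), , drop = FALSE]
  lf <- stats::lm.fit(cbind(1, edges$row), edges$left)$coefficients[2L]
  rf <- stats::lm.fit(cbind(1, edges$row), edges$right)$coefficients[2L]
  # angle of each envelope from the downward vertical; apex angle is the
  # difference (right slope positive / left negative for an opening cone)
  ra <- unname((atan(rf) - atan(lf)) * 180 / pi)
  if (!is.finite(ra) || ra <= 0) {
    stop("no root cone detected: envelope lines do not open downward")
  }
  list(RA = ra, left_slope = unname(lf), right_slope = unname(rf))
}

#' Phenotype every view of a sample
#'
#' Runs the fractal estimation on the underside view and the architecture
#' measurements on each side view, returning the per-view values plus the
#' plot-level aggregate: RA and SD are arithmetic means over the valid
#' side views (sub-sampling four perspectives reduces the bias of a single
#' 2-D projection of a 3-D structure), while FD and FA come from the
#' underside image only (fractal estimates from different perspectives of
#' one sample are nearly perfectly correlated, so one suffices).
#'
#' @param views A `view_set` from [project_views()], or a list with
#'   `side_views` (named list of `binary_image`) and `underside`.
#' @param box_sizes Scale ladder passed to [box_count()].
#' @param flare_factor,band_frac Passed to the architecture measurements.
#' @return A list of class `sample_phenotype` with elements `FD`, `FA`,
#'   `RA`, `SD`, `fit_r2`, and `per_view` (data frame of per-view RA/SD
#'   and per-view status).
#' @export
aggregate_sample <- function(views, box_sizes = 2L^(0:9),
                             flare_factor = 1.5, band_frac = 0.05) {
  stopifnot(!is.null(views$underside), length(views$side_views) >= 1L)
  fr <- fit_fractal(box_count(views$underside, box_sizes))
  per_view <- lapply(names(views$side_views), function(tag) {
    sv <- views$side_views[[tag]]
    res <- try({
      sd_v <- measure_stalk_diameter(sv, flare_factor, band_frac)
      ra_v <- measure_root_angle(sv, flare_factor, band_frac)
      data.frame(view = tag, RA = ra_v$RA, SD = sd_v$SD, status = "ok")
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      data.frame(view = tag, RA = NA_real_, SD = NA_real_,
                 status = conditionMessage(attr(res, "condition")))
    } else res
  })
  per_view <- do.call(rbind, per_view)
  ok <- per_view$status == "ok"
  structure(list(FD = fr$FD, FA = fr$FA, K = fr$K, fit_r2 = fr$fit_r2,
                 RA = if (any(ok)) mean(per_view$RA[ok]) else NA_real_,
                 SD = if (any(ok)) mean(per_view$SD[ok]) else NA_real_,
                 per_view = per_view),
            class = "sample_phenotype")
}

#' @export
print.sample_phenotype <- function(x, ...) {
  cat(sprintf("<sample_phenotype FD=%.3f FA=%.3f RA=%.1f SD=%.1f (%d/%d views ok)>\n",
              x$FD, x$FA, x$RA, x$SD, sum(x$per_view$status == "ok"),
              nrow(x$per_view)))
  invisible(x)
}

#' Filter phenotype records for image-processing outliers
#'
#' Screens a per-view phenotype table for records attributable to image
#' processing difficulties. A view is dropped when its box-count fit is
#' poor (`fit_r2 < r2_min`) or when any screened trait deviates more than
#' `mad_k` median-absolute-deviations from its plot median (computed over
#' the views of the same plot). A plot is marked missing only when all of
#' its views fail. Every removal is logged with its reason.
#'
#' @param records Data frame with columns `plot_id`, `view`, trait
#'   columns, and optionally `fit_r2`.
#' @param traits Character vector of trait columns to screen (default all
#'   of FD, FA, RA, SD that are present).
#' @param r2_min Minimum acceptable box-count fit r-squared (default 0.95).
#' @param mad_k MAD multiple beyond which a view's trait is an outlier
#'   (default 4).
#' @return A list with `records` (the retained rows), `removed` (dropped
#'   rows with a `reason` column), and `missing_plots` (plot ids whose
#'   views all failed).
#' @export
filter_outliers <- function(records, traits = intersect(
                              c("FD", "FA", "RA", "SD"), names(records)),
                            r2_min = 0.95, mad_k = 4) {
  stopifnot("plot_id" %in% names(records))
  reason <- rep(NA_character_, nrow(records))
  if ("fit_r2" %in% names(records)) {
    bad <- !is.na(records$fit_r2) & records$fit_r2 < r2_min
    reason[bad] <- sprintf("fit_r2 %.3f < %.2f", records$fit_r2[bad], r2_min)
  }
  for (tr in traits) {
    v <- records[[tr]]
    med <- stats::ave(v, records$plot_id,
                      FUN = function(x) stats::median(x, na.rm = TRUE))
    madv <- stats::ave(v, records$plot_id,
                       FUN = function(x) stats::mad(x, na.rm = TRUE))
    bad <- is.na(reason) & !is.na(v) & madv > 0 & abs(v - med) > mad_k * madv
    reason[bad] <- sprintf("%s deviates > %g MAD from plot median", tr, mad_k)
  }
  keep <- is.na(reason)
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!keep]
  else removed$reason <- character(0)
  kept <- records[keep, , drop = FALSE]
  missing_plots <- setdiff(unique(records$plot_id), unique(kept$plot_id))
  list(records = kept, removed = removed, missing_plots = missing_plots)
}
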