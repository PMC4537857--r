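test_that("binarization follows the strictly-greater threshold convention", {
  img <- matrix(0.2, 8, 8)
  img[3, 3] <- 0.5    # exactly at threshold -> background
  img[4, 4] <- 0.7
  bi <- preprocess(img, threshold = 0.5)
  expect_false(bi[3, 3])
  expect_true(bi[4, 4])
  expect_error(preprocess(matrix(0.2, 8, 8), threshold = 0.5), "empty")
})

test_that("background subtraction recovers a pasted silhouette exactly", {
  bg <- matrix(0.35, 128, 128)
  truth <- mask_of(render_known_fractal("sierpinski_triangle", 128,
                                        level = 5))
  raw <- bg
  raw[truth] <- 0.95
  bi <- preprocess(raw, threshold = 0.3, background = bg)
  expect_identical(mask_of(bi), truth)
})

test_that("stalk diameter is the mean width of the pre-flare band", {
  bar <- matrix(FALSE, 128, 128)
  bar[1:100, 45:84] <- TRUE                       # 40-px vertical bar
  expect_equal(measure_stalk_diameter(binary_image(bar))$SD, 40,
               tolerance = 0.5)

  flared <- bar
  flared[60:128, 20:109] <- TRUE                  # wide flare below row 60
  res <- measure_stalk_diameter(binary_image(flared))
  expect_equal(res$SD, 40, tolerance = 1)          # flare excluded
  expect_lt(res$stalk_rows[2], 60)

  empty_top <- matrix(FALSE, 128, 128)
  empty_top[100:128, 45:84] <- TRUE
  expect_error(measure_stalk_diameter(binary_image(empty_top)),
               "no stalk detected")
})

test_that("root angle recovers analytically known wedge apex angles", {
  expect_equal(measure_root_angle(make_wedge(45))$RA, 90, tolerance = 2)
  expect_equal(measure_root_angle(make_wedge(30))$RA, 60, tolerance = 2)
  expect_equal(measure_root_angle(make_wedge(20))$RA, 40, tolerance = 2)
  # robust envelope agrees on clean wedges
  expect_equal(measure_root_angle(make_wedge(30), robust = TRUE)$RA, 60,
               tolerance = 3)
})

test_that("stem-only images raise a no-root-cone error", {
  bar <- matrix(FALSE, 128, 128)
  bar[1:128, 55:74] <- TRUE
  expect_error(measure_root_angle(binary_image(bar)), "no root cone")
})

test_that("sample aggregation averages side views and uses the underside", {
  v <- project_views(grow_root_system(growth_params(rng_seed = 11,
                                                    canvas_size_px = 256)))
  ph <- aggregate_sample(v, box_sizes = 2L^(0:8))
  ok <- ph$per_view$status == "ok"
  expect_true(all(ok))
  expect_equal(ph$RA, mean(ph$per_view$RA))
  expect_equal(ph$SD, mean(ph$per_view$SD))
  und <- fit_fractal(box_count(v$underside, 2L^(0:8)))
  expect_identical(ph$FD, und$FD)                 # FD from underside only
  # four identical views -> the mean equals each view
  v4 <- v
  v4$side_views <- v$side_views[c(1, 1, 1, 1)]
  names(v4$side_views) <- names(v$side_views)
  ph4 <- aggregate_sample(v4, box_sizes = 2L^(0:8))
  expect_equal(ph4$RA, ph4$per_view$RA[1])
})

test_that("projected cone angle is recovered within tolerance on average", {
  ens <- root_sample_ensemble(36L)
  err <- ens$ra_mean - 2 * ens$half_angle
  expect_lt(mean(abs(err), na.rm = TRUE), 5)
})

test_that("single-view and four-view root angles are highly correlated", {
  ens <- root_sample_ensemble(50L)
  r <- cor(ens$ra_0, ens$ra_mean, use = "complete.obs")
  expect_gte(r, 0.8)
})

test_that("FD from orthogonal side views agrees across an ensemble", {
  ens <- root_sample_ensemble(50L)
  expect_gte(cor(ens$fd_side_0, ens$fd_side_90), 0.8)
})

test_that("outlier filtering drops flagged views but keeps the plot", {
  rec <- data.frame(plot_id = rep(c("p1", "p2"), each = 4),
                    view = rep(c("0", "90", "180", "270"), 2),
                    RA = c(70, 71, 69, 70, 80, 81, 79, 80),
                    SD = c(40, 41, 39, 40, 50, 51, 49, 50),
                    fit_r2 = c(0.99, 0.99, 0.99, 0.99,
                               0.5, 0.99, 0.99, 0.99))
  res <- filter_outliers(rec)
  expect_equal(nrow(res$removed), 1L)
  expect_match(res$removed$reason, "fit_r2")
  expect_length(res$missing_plots, 0L)

  clean <- filter_outliers(rec[rec$plot_id == "p1", ])
  expect_equal(nrow(clean$removed), 0L)
  expect_identical(clean$records, rec[rec$plot_id == "p1", ])

  allbad <- rec[rec$plot_id == "p2", ]
  allbad$fit_r2 <- 0.3
  res2 <- filter_outliers(allbad)
  expect_equal(res2$missing_plots, "p2")   # missing, not zero-filled
  expect_equal(nrow(res2$records), 0L)
})

test_that("trait outliers beyond 4 MAD of the plot median are removed", {
  set.seed(3)
  rec <- data.frame(plot_id = "p1", view = as.character(1:8),
                    RA = c(70, 71, 69, 70, 71, 69, 70, 140),
                    SD = 40, fit_r2 = 0.99)
  res <- filter_outliers(rec)
  expect_equal(res$removed$view, "8")
  expect_match(res$removed$reason, "MAD")
})
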