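test_that("pairwise correlations match the textbook formula", {
  set.seed(14)
  rec <- data.frame(entry_class = "F1",
                    t1 = rnorm(40), t2 = rnorm(40), t3 = rnorm(40))
  rec$t2 <- rec$t2 + 0.8 * rec$t1
  cc <- class_correlations(rec, c("t1", "t2", "t3"), "F1")
  oracle_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc$r["t1", "t2"], oracle_r(rec$t1, rec$t2), tolerance = 1e-12)
  expect_equal(cc$r, t(cc$r))
  expect_true(all(diag(cc$r) == 1))
  # perfect dependence
  rec2 <- data.frame(entry_class = "F1", x = 1:10, y = 1:10, z = -(1:10))
  cc2 <- class_correlations(rec2, c("x", "y", "z"), "F1")
  expect_equal(cc2$r["x", "y"], 1)
  expect_equal(cc2$r["x", "z"], -1)
  # PSD within tolerance
  expect_gte(min(eigen(cc$r, symmetric = TRUE)$values), -1e-8)
  expect_error(class_correlations(data.frame(entry_class = "F1", a = 1:5,
                                             b = rep(2, 5)),
                                  c("a", "b"), "F1"), "constant")
})

test_that("maturity adjustment removes the linear flowering-time trend", {
  set.seed(5)
  dts <- rnorm(60, 70, 4)
  b <- 0.8
  trait <- 10 + b * dts + rnorm(60, 0, 0.5)
  adj <- maturity_adjust(trait, dts)
  expect_lt(abs(adj$slope - b), 3 * adj$slope_se)
  expect_lt(abs(cor(adj$adjusted, dts)), 0.1)
  expect_equal(mean(adj$adjusted), mean(trait), tolerance = 1e-10)

  exact <- 2 + 3 * dts
  adj2 <- suppressWarnings(maturity_adjust(exact, dts))
  expect_equal(adj2$adjusted, rep(mean(exact), 60), tolerance = 1e-10)

  unrelated <- rnorm(60)
  adj3 <- maturity_adjust(unrelated, dts)
  expect_equal(adj3$adjusted, unrelated, tolerance = 0.5)
  expect_error(maturity_adjust(trait, rep(70, 60)), "constant")
})

test_that("z-scoring standardizes columns and is idempotent", {
  set.seed(9)
  X <- matrix(rnorm(60, 5, 3), 20, 3)
  Z <- zscore(X)
  expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unclass(zscore(Z)), unclass(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(zscore(X + 7)), unclass(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(zscore(cbind(X, rep(1, 20))), "zero-variance")
})

test_that("correlation PCA has closed-form structure", {
  set.seed(21)
  X <- matrix(rnorm(300), 100, 3)          # independent traits
  pc <- pca_correlation(X)
  expect_equal(sum(pc$eigenvalues), 3, tolerance = 1e-10)
  expect_true(all(abs(pc$eigenvalues - 1) < 0.35))

  # two traits with known r: eigenvalues 1 +/- r
  r_target <- 0.9
  n <- 5000
  x <- rnorm(n)
  y <- r_target * x + sqrt(1 - r_target^2) * rnorm(n)
  pc2 <- pca_correlation(cbind(x, y))
  r_hat <- cor(x, y)
  expect_equal(pc2$eigenvalues, c(1 + r_hat, 1 - r_hat), tolerance = 1e-10)
  # orthonormal loadings, sign convention
  expect_equal(crossprod(pc2$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(apply(pc2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("a planted one-factor structure loads on PC1", {
  set.seed(33)
  n <- 80
  f <- rnorm(n)
  w <- c(1, 1, -1, 1, -1)                   # planted loading signs
  X <- sapply(seq_along(w), function(j) w[j] * f + 0.4 * rnorm(n))
  pc <- pca_correlation(X)
  expect_gt(pc$variance_explained[1], 0.5)
  l1 <- pc$loadings[, 1]
  expect_true(all(sign(l1) == sign(w) * sign(sum(l1 * w))))
})

test_that("clustering recovers separated groups and ignores labels/order", {
  set.seed(12)
  centers <- rbind(c(0, 0), c(30, 0), c(0, 30))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(40, 0, 1), 20, 2), 2, centers[k, ], `+`)
  }))
  rownames(X) <- sprintf("e%02d", seq_len(nrow(X)))
  cl <- hcluster(X, k = 3)
  truth <- rep(1:3, each = 20)
  expect_equal(length(unique(paste(cl$labels, truth))), 3L)  # perfect match

  # permutation invariance of the partition
  perm <- sample(nrow(X))
  cl_p <- hcluster(X[perm, ], k = 3)
  expect_equal(length(unique(paste(cl_p$labels[rownames(X)],
                                   cl$labels[rownames(X)]))), 3L)

  # duplicated points merge at height zero
  dup <- rbind(X[1:5, ], X[1:5, ])
  rownames(dup) <- sprintf("d%02d", 1:10)
  cl_d <- hcluster(dup, k = 5)
  expect_equal(min(cl_d$tree$height), 0)
  expect_error(hcluster(X, k = 100), "exceeds")
})
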