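make_small_design <- function(parents = paste0("P", 1:4),
                              checks = c("K1", "K2"),
                              envs = c("E1", "E2"), reps = 2) {
  spec <- diallel_spec(parents, checks, envs, reps)
  sim <- diallel_sim_spec(parent_ids = parents, check_ids = checks,
                          env_ids = envs, reps_per_env = reps)
  keys <- simulate_diallel_dataset(sim)
  list(spec = spec, keys = keys, design = build_design(spec, keys))
}

test_that("design rows carry the entry-class genetic coefficients", {
  d <- make_small_design()
  X <- d$design$X
  b <- d$design$bases
  keys <- d$keys
  a_cols <- d$design$terms$lines_per_se
  g_cols <- d$design$terms$gca
  s_cols <- d$design$terms$sca
  i_par <- which(keys$entry_class == "parent" & keys$parent1 == "P2")[1]
  expect_equal(unname(X[i_par, a_cols]), unname(b$parent["P2", ]))
  expect_true(all(X[i_par, c(g_cols, s_cols)] == 0))

  i_f1 <- which(keys$entry_class == "F1" & keys$parent1 == "P1" &
                  keys$parent2 == "P3")[1]
  expect_equal(unname(X[i_f1, a_cols]),
               unname(0.5 * (b$parent["P1", ] + b$parent["P3", ])))
  expect_equal(unname(X[i_f1, g_cols]),
               unname(b$parent["P1", ] + b$parent["P3", ]))
  expect_equal(unname(X[i_f1, s_cols]), unname(b$sca["P1:P3", ]))

  i_chk <- which(keys$entry_class == "check")[1]
  expect_true(all(X[i_chk, c(a_cols, g_cols, s_cols)] == 0))
})

test_that("12-parent design has the canonical genetic degrees of freedom", {
  spec <- root_trait_sim_spec("FD", rng_seed = 1)
  keys <- simulate_diallel_dataset(spec)
  dspec <- diallel_spec(spec$parent_ids, spec$check_ids, spec$env_ids,
                        spec$reps_per_env)
  des <- build_design(dspec, keys)
  expect_length(dspec$crosses, 66L)
  expect_length(des$terms$lines_per_se, 11L)
  expect_length(des$terms$gca, 11L)
  expect_length(des$terms$sca, 54L)
  expect_length(des$terms$line_x_env, 11L)
  expect_equal(length(des$terms$lines_per_se) + length(des$terms$gca) +
                 length(des$terms$sca), 76L)
  expect_equal(qr(des$X)$rank, ncol(des$X))   # full rank when balanced
})

test_that("design construction validates ids and cross ordering", {
  d <- make_small_design()
  bad <- d$keys
  bad$parent1[1] <- "NOPE"
  expect_error(build_design(d$spec, bad), "unknown parent")
  swp <- d$keys
  i <- which(swp$entry_class == "F1")[1]
  tmp <- swp$parent1[i]
  swp$parent1[i] <- swp$parent2[i]
  swp$parent2[i] <- tmp
  expect_error(build_design(d$spec, swp), "reciprocal")
})

test_that("noise-free data returns every true effect to machine precision", {
  true_h <- 0.9
  spec <- diallel_sim_spec(
    parent_ids = paste0("P", 1:6), check_ids = c("K1", "K2", "K3"),
    env_ids = c("E1", "E2"), reps_per_env = 3, mu = 10,
    env = c(E1 = 0.4, E2 = -0.4),
    class_effect = c(parent = -true_h / 2, F1 = true_h / 2, check = 0),
    a = c(P1 = 0.5, P2 = -0.3, P3 = 0.2, P4 = -0.1, P5 = -0.25,
          P6 = -0.05),
    g = c(P1 = 0.1, P2 = 0.05, P3 = -0.05, P4 = -0.1, P5 = 0.02,
          P6 = -0.02),
    check = c(K1 = 0.3, K2 = -0.1, K3 = -0.2))
  # add a valid random SCA vector
  set.seed(8)
  spec$s <- rootdiallel:::project_sca_sum_zero(
    stats::setNames(rnorm(15, 0, 0.2), names(spec$s)), spec$parent_ids)
  dat <- simulate_diallel_dataset(spec)
  des <- build_design(diallel_spec(spec$parent_ids, spec$check_ids,
                                   spec$env_ids, spec$reps_per_env), dat)
  fit <- fit_diallel(dat, des, "y")
  ge <- genetic_effects(fit)
  expect_equal(ge$lines$a, unname(spec$a[ge$lines$level]),
               tolerance = 1e-10)
  expect_equal(ge$lines$g, unname(spec$g[ge$lines$level]),
               tolerance = 1e-10)
  expect_equal(ge$sca$estimate, unname(spec$s[ge$sca$level]),
               tolerance = 1e-10)
  expect_equal(ge$checks$estimate, unname(spec$check[ge$checks$level]),
               tolerance = 1e-10)
  ct <- estimate_contrasts(fit)
  expect_equal(ct$estimate[ct$contrast == "heterosis"], true_h,
               tolerance = 1e-10)
  expect_equal(ct$estimate[ct$contrast == "env_difference"], 0.8,
               tolerance = 1e-10)
  # balanced zero-noise: class least-square means equal block means
  ge_means <- ge$class_means
  for (cl in c("parent", "F1", "check")) {
    expect_equal(ge_means$lsmean[ge_means$entry_class == cl],
                 mean(dat$y[dat$entry_class == cl]), tolerance = 1e-10)
  }
})

test_that("unbalanced fits match a pseudoinverse normal-equations oracle", {
  skip_if_not_installed("MASS")
  spec <- root_trait_sim_spec("RA", rng_seed = 7)
  dat <- simulate_diallel_dataset(spec)
  set.seed(11)
  dat$RA[sample(nrow(dat), round(0.1 * nrow(dat)))] <- NA
  des <- build_design(diallel_spec(spec$parent_ids, spec$check_ids,
                                   spec$env_ids, spec$reps_per_env), dat)
  fit <- fit_diallel(dat, des, "RA")
  X <- des$X[fit$used, ]
  y <- dat$RA[fit$used]
  beta <- drop(MASS::ginv(crossprod(X)) %*% crossprod(X, y))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
})

test_that("Type III tests are invariant to shifts and entry permutations", {
  spec <- root_trait_sim_spec("FD", rng_seed = 4)
  dat <- simulate_diallel_dataset(spec)
  des <- build_design(diallel_spec(spec$parent_ids, spec$check_ids,
                                   spec$env_ids, spec$reps_per_env), dat)
  fit <- fit_diallel(dat, des, "FD")
  av <- type3_anova(fit)
  expect_setequal(
    av$term,
    c("env", "rep_in_env", "entry_class", "lines_per_se", "gca", "sca",
      "checks", "env_x_class", "rep_x_class", "line_x_env", "check_x_env"))

  # adding a constant moves only the intercept
  dat2 <- dat
  dat2$FD <- dat$FD + 100
  fit2 <- fit_diallel(dat2, des, "FD")
  av2 <- type3_anova(fit2)
  expect_equal(av2$F, av$F, tolerance = 1e-8)
  expect_equal(fit2$coefficients["(Intercept)"],
               fit$coefficients["(Intercept)"] + 100, tolerance = 1e-8)

  # permuting plot order changes nothing
  set.seed(20)
  perm <- sample(nrow(dat))
  des_p <- build_design(diallel_spec(spec$parent_ids, spec$check_ids,
                                     spec$env_ids, spec$reps_per_env),
                        dat[perm, ])
  fit_p <- fit_diallel(dat[perm, ], des_p, "FD")
  av_p <- type3_anova(fit_p)
  expect_equal(av_p$F[match(av$term, av_p$term)], av$F, tolerance = 1e-8)
  expect_error(type3_anova(fit, terms = "no_such_term"), "absent")
})

test_that("null simulations give calibrated F tests and uniform p-values", {
  parents <- paste0("P", 1:8)
  sim <- diallel_sim_spec(parent_ids = parents, check_ids = c("K1", "K2"),
                          env_ids = c("E1", "E2"), reps_per_env = 2)
  keys <- simulate_diallel_dataset(sim)
  des <- build_design(diallel_spec(parents, c("K1", "K2"),
                                   c("E1", "E2"), 2), keys)
  n_rep <- 300L
  res <- with_seed_local(42, {
    t(vapply(seq_len(n_rep), function(i) {
      keys$y <- rnorm(nrow(keys))
      fit <- fit_diallel(keys, des, "y")
      av <- type3_anova(fit, terms = c("gca", "sca"))
      c(F_gca = av$F[1], p_gca = av$p[1], F_sca = av$F[2], p_sca = av$p[2])
    }, numeric(4)))
  })
  expect_equal(mean(res[, "F_gca"]), 1, tolerance = 0.15)
  expect_equal(mean(res[, "F_sca"]), 1, tolerance = 0.15)
  expect_gt(ks.test(res[, "p_gca"], "punif")$p.value, 0.01)
  expect_gt(ks.test(res[, "p_sca"], "punif")$p.value, 0.01)
})

test_that("planted heterosis and additive effects are recovered under noise", {
  n_seeds <- 200L
  truth <- root_trait_sim_spec("RA", rng_seed = 1)
  true_h <- unname(truth$class_effect["F1"] - truth$class_effect["parent"])
  dspec <- diallel_spec(truth$parent_ids, truth$check_ids, truth$env_ids,
                        truth$reps_per_env)
  ests <- vapply(seq_len(n_seeds), function(i) {
    spec <- truth
    spec$rng_seed <- 5000L + i
    dat <- simulate_diallel_dataset(spec)
    des <- build_design(dspec, dat)
    fit <- fit_diallel(dat, des, "RA")
    ct <- estimate_contrasts(fit)
    c(ct$estimate[ct$contrast == "heterosis"],
      genetic_effects(fit)$lines$a[1])
  }, numeric(2))
  mc_se <- sd(ests[1, ]) / sqrt(n_seeds)
  expect_lt(abs(mean(ests[1, ]) - true_h), 3 * mc_se)
  true_a1 <- unname(truth$a[dspec$parent_ids[1]])
  mc_se_a <- sd(ests[2, ]) / sqrt(n_seeds)
  expect_lt(abs(mean(ests[2, ]) - true_a1), 3 * mc_se_a)
})

test_that("adaptive FDR matches a direct step-up oracle and its bounds", {
  fdr_oracle <- function(p, alpha = 0.05) {
    m <- length(p)
    ord <- order(p)
    # stage 1: plain step-up at alpha/(1+alpha) to estimate m0
    bh <- rep(NA_real_, m)
    sorted <- p[ord]
    q_raw <- m * sorted / seq_len(m)
    q_sorted <- rev(cummin(rev(q_raw)))
    r1 <- sum(sorted <= seq_len(m) * (alpha / (1 + alpha)) / m)
    m0 <- max(1, m - r1)
    q2 <- rev(cummin(rev(m0 * sorted / seq_len(m))))
    out <- numeric(m)
    out[ord] <- pmin(1, q2)
    out
  }
  set.seed(31)
  for (rep in 1:5) {
    p <- runif(50)^runif(1, 0.5, 3)
    expect_equal(adjust_fdr(p), fdr_oracle(p), tolerance = 1e-12)
  }
  expect_equal(adjust_fdr(0.37), 0.37)              # single p -> q = p
  expect_equal(adjust_fdr(rep(0.02, 7)), rep(adjust_fdr(rep(0.02, 7))[1], 7))
  # monotone transform of p, never above 1, adaptive <= plain step-up
  p <- c(1e-6, 1e-4, 0.003, 0.2, 0.4, 0.9)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1 & q >= 0))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("repeatability follows the expected-mean-squares plug-in", {
  # no GxE, no residual noise -> R = 1
  g <- rep(rnorm(10, 0, 2), each = 4)
  d0 <- data.frame(entry_id = rep(paste0("G", 1:10), each = 4),
                   env = rep(c("E1", "E1", "E2", "E2"), 10),
                   rep = rep(c("R1", "R2"), 20), y = g)
  expect_equal(suppressWarnings(repeatability(d0, "y"))$R, 1)

  # no genetic variance -> R near 0
  set.seed(6)
  d1 <- d0
  d1$y <- rnorm(40)
  expect_lt(repeatability(d1, "y")$R, 0.5)

  # simulated components: estimate close to the plug-in truth
  set.seed(77)
  nG <- 40; nE <- 2; nR <- 3
  s2g <- 4; s2ge <- 1; s2e <- 2
  ge <- matrix(rnorm(nG * nE, 0, sqrt(s2ge)), nG, nE)
  gg <- rnorm(nG, 0, sqrt(s2g))
  dd <- expand.grid(G = seq_len(nG), E = seq_len(nE), R = seq_len(nR))
  dd$y <- gg[dd$G] + ge[cbind(dd$G, dd$E)] + rnorm(nrow(dd), 0, sqrt(s2e))
  d2 <- data.frame(entry_id = paste0("G", dd$G), env = paste0("E", dd$E),
                   rep = paste0("R", dd$R), y = dd$y)
  R_true <- s2g / (s2g + s2ge / nE + s2e / (nE * nR))
  expect_equal(repeatability(d2, "y")$R, R_true, tolerance = 0.15)
  expect_error(repeatability(d2[d2$env == "E1", ], "y"), "2 environments")
})
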