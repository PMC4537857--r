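#' Fit the diallel model by constrained least squares
#'
#' Ordinary least squares of one trait on a [build_design()] matrix. All
#' genetic parameters are fixed effects. Rows with a missing trait value
#' are dropped (trial data with lost plots gives an unbalanced design);
#' rank deficiency arising from missingness is handled by pivoted QR, with
#' non-estimable coefficients flagged (`NA` estimates).
#'
#' @param data Data frame holding the trait column; must have the same
#'   rows (and order) as the `keys` used to build the design.
#' @param design A `diallel_design`.
#' @param trait Name of the trait column in `data`.
#' @return A list of class `diallel_fit`: `coefficients`, `se`, `vcov`
#'   (estimable block), `sigma2`, `df_residual`, `rank`, `fitted`,
#'   `residuals`, `used` (logical row filter), `trait`, `design`.
#' @export
fit_diallel <- function(data, design, trait) {
  stopifnot(inherits(design, "diallel_design"))
  if (!trait %in% names(data)) stop("trait column not found: ", trait)
  if (nrow(data) != nrow(design$X)) {
    stop("data rows (", nrow(data), ") do not match design rows (",
         nrow(design$X), ")")
  }
  y <- data[[trait]]
  used <- !is.na(y)
  if (!any(used)) stop("all values missing for trait ", trait)
  X <- design$X[used, , drop = FALSE]
  y <- y[used]
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  if (r == 0L) stop("design has rank 0")
  df_res <- sum(used) - r
  sigma2 <- if (df_res > 0) sum(fit$residuals^2) / df_res else 0
  coefs <- fit$coefficients          # NA for aliased columns
  piv <- fit$qr$pivot[seq_len(r)]
  Rmat <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  XtXinv <- chol2inv(Rmat)
  V <- matrix(NA_real_, ncol(X), ncol(X),
              dimnames = list(colnames(X), colnames(X)))
  V[piv, piv] <- sigma2 * XtXinv
  se <- sqrt(diag(V))
  structure(list(coefficients = coefs, se = se, vcov = V,
                 sigma2 = sigma2, df_residual = df_res, rank = r,
                 rss = sum(fit$residuals^2),
                 fitted = fit$fitted.values, residuals = fit$residuals,
                 used = used, trait = trait, design = design),
            class = "diallel_fit")
}

#' @export
print.diallel_fit <- function(x, ...) {
  cat(sprintf(
    "<diallel_fit '%s': %d plots, rank %d, residual df %d, sigma2 %.4g>\n",
    x$trait, sum(x$used), x$rank, x$df_residual, x$sigma2))
  invisible(x)
}

#' Type III tests of the diallel model terms
#'
#' Per-term F tests by full-versus-reduced model comparison: the reduced
#' model omits exactly the sum-to-zero columns of that term while keeping
#' every other term, which under this coding tests each term adjusted for
#' all others (the marginal, "Type III" hypothesis). P-values are FDR
#' adjusted across the table with [adjust_fdr()].
#'
#' @param fit A `diallel_fit`.
#' @param terms Character vector of term names to test; defaults to every
#'   non-intercept term of the design.
#' @return Data frame with columns `term`, `df`, `F`, `p`, `q`, and
#'   `stars` (significance at q <= 0.001/0.01/0.05/0.1).
#' @export
type3_anova <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "diallel_fit"))
  design <- fit$design
  all_terms <- setdiff(names(design$terms), "(Intercept)")
  if (is.null(terms)) terms <- all_terms
  missing_terms <- setdiff(terms, all_terms)
  if (length(missing_terms)) {
    stop("term absent from design: ", paste(missing_terms, collapse = ", "))
  }
  X <- design$X[fit$used, , drop = FALSE]
  y_fitted_plus_res <- fit$fitted + fit$residuals
  rss_full <- fit$rss
  rows <- lapply(terms, function(tm) {
    drop_cols <- design$terms[[tm]]
    Xr <- X[, -drop_cols, drop = FALSE]
    fr <- stats::lm.fit(Xr, y_fitted_plus_res)
    df_term <- fit$rank - fr$rank
    if (df_term <= 0L) {
      return(data.frame(term = tm, df = 0L, F = NA_real_, p = NA_real_))
    }
    Fval <- ((sum(fr$residuals^2) - rss_full) / df_term) /
      (rss_full / fit$df_residual)
    data.frame(term = tm, df = df_term, F = Fval,
               p = stats::pf(Fval, df_term, fit$df_residual,
                             lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$q <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p)
  out$q[ok] <- adjust_fdr(out$p[ok])
  out$stars <- significance_stars(out$q)
  out
}

significance_stars <- function(q) {
  ifelse(is.na(q), "",
  ifelse(q <= 0.001, "***",
  ifelse(q <= 0.01, "**",
  ifelse(q <= 0.05, "*",
  ifelse(q <= 0.1, "○", "")))))
}

# Recover a full (sum-to-zero) effect vector and its SEs from the fitted
# free coefficients of one family.
recover_effects <- function(fit, term, basis) {
  idx <- fit$design$terms[[term]]
  if (is.null(idx)) stop("term absent from design: ", term)
  theta <- fit$coefficients[idx]
  if (anyNA(theta)) {
    warning("non-estimable coefficients in term ", term,
            "; recovered effects are NA")
    return(data.frame(level = rownames(basis),
                      estimate = NA_real_, se = NA_real_))
  }
  est <- drop(basis %*% theta)
  V <- basis %*% fit$vcov[idx, idx, drop = FALSE] %*% t(basis)
  data.frame(level = rownames(basis), estimate = est,
             se = sqrt(pmax(0, diag(V))))
}

#' Genetic effect estimates from a diallel fit
#'
#' Recovers the full sum-to-zero effect vectors: additive line effects per
#' se `a_l`, general combining abilities `g_l`, specific combining
#' abilities `s_lm`, and check effects, each with standard error, t test
#' against zero, and adaptive-FDR q-value (adjusted within each family).
#' Entry-class least-square means (`mu` + class effect) are included.
#'
#' @param fit A `diallel_fit`.
#' @return A list of class `genetic_effects` with data frames `lines`
#'   (columns `level`, `a`, `a_se`, `a_q`, `g`, `g_se`, `g_q`, stars),
#'   `sca`, `checks`, and `class_means`.
#' @export
genetic_effects <- function(fit) {
  b <- fit$design$bases
  add_tests <- function(df) {
    tt <- df$estimate / df$se
    df$p <- 2 * stats::pt(abs(tt), fit$df_residual, lower.tail = FALSE)
    df$q <- adjust_fdr(df$p)
    df$stars <- significance_stars(df$q)
    df
  }
  a <- add_tests(recover_effects(fit, "lines_per_se", b$parent))
  g <- add_tests(recover_effects(fit, "gca", b$parent))
  s <- add_tests(recover_effects(fit, "sca", b$sca))
  chk <- if ("checks" %in% names(fit$design$terms)) {
    add_tests(recover_effects(fit, "checks", b$check))
  } else NULL
  lines <- data.frame(level = a$level,
                      a = a$estimate, a_se = a$se, a_q = a$q,
                      a_stars = a$stars,
                      g = g$estimate, g_se = g$se, g_q = g$q,
                      g_stars = g$stars)
  cls <- recover_effects(fit, "entry_class", b$class)
  mu <- fit$coefficients["(Intercept)"]
  cls_means <- data.frame(entry_class = cls$level,
                          lsmean = mu + cls$estimate,
                          se = cls$se)
  structure(list(lines = lines, sca = s, checks = chk,
                 class_means = cls_means, trait = fit$trait),
            class = "genetic_effects")
}

#' Entry-class contrasts: heterosis, F1 vs checks, environments
#'
#' The entry-class (generation block) effects partition into orthogonal
#' single-degree-of-freedom contrasts: mean mid-parent heterosis, the F1
#' blocks mean minus the parents blocks mean; and the mean difference
#' between the diallel F1s and the commercial checks, the F1s mean minus
#' the checks mean. The environment difference (first minus second
#' environment class mean) is reported alongside. Standard errors come
#' from the fit covariance; p-values are t tests and q-values are
#' adaptive-FDR adjusted across the reported contrasts.
#'
#' @param fit A `diallel_fit`.
#' @return Data frame with columns `contrast`, `estimate`, `se`, `p`,
#'   `q`, `stars`.
#' @export
estimate_contrasts <- function(fit) {
  b <- fit$design$bases
  recover_contrast <- function(term, basis, w) {
    idx <- fit$design$terms[[term]]
    theta <- fit$coefficients[idx]
    cvec <- drop(crossprod(basis, w))     # contrast in free-coef space
    est <- sum(cvec * theta)
    se <- sqrt(drop(t(cvec) %*% fit$vcov[idx, idx] %*% cvec))
    c(estimate = est, se = se)
  }
  classes <- rownames(b$class)
  w_het <- (classes == "F1") - (classes == "parent")
  w_f1c <- (classes == "F1") - (classes == "check")
  rows <- list(
    heterosis = recover_contrast("entry_class", b$class, w_het),
    F1_vs_checks = recover_contrast("entry_class", b$class, w_f1c))
  if (length(fit$design$spec$env_ids) >= 2L) {
    envs <- rownames(b$env)
    w_env <- (envs == envs[1L]) - (envs == envs[2L])
    rows$env_difference <- recover_contrast("env", b$env, w_env)
  }
  out <- data.frame(contrast = names(rows),
                    estimate = vapply(rows, `[[`, numeric(1), "estimate"),
                    se = vapply(rows, `[[`, numeric(1), "se"),
                    row.names = NULL)
  tt <- out$estimate / out$se
  out$p <- 2 * stats::pt(abs(tt), fit$df_residual, lower.tail = FALSE)
  out$q <- adjust_fdr(out$p)
  out$stars <- significance_stars(out$q)
  out
}

#' Class-mean contrast arithmetic
#'
#' Computes the generation-block contrasts directly from entry-class
#' means: mean mid-parent heterosis (F1 mean minus parent mean) and the
#' F1-versus-check difference. Useful for reconciling published class
#' means with published contrast estimates.
#'
#' @param class_means Named numeric vector with elements `parent`, `F1`,
#'   and optionally `check`.
#' @return Named numeric vector with `heterosis` and (when a check mean
#'   is present) `F1_vs_checks`.
#' @examples
#' class_mean_contrasts(c(parent = 1.756, F1 = 1.794, check = 1.803))
#' @export
class_mean_contrasts <- function(class_means) {
  stopifnot(all(c("parent", "F1") %in% names(class_means)))
  out <- c(heterosis = unname(class_means["F1"] - class_means["parent"]))
  if ("check" %in% names(class_means)) {
    out["F1_vs_checks"] <- unname(class_means["F1"] - class_means["check"])
  }
  out
}

#' Adaptive false discovery rate adjustment
#'
#' Adaptive linear step-up q-values: a first-stage linear step-up pass at
#' level `alpha/(1 + alpha)` estimates the number of true nulls as
#' `m0 = m - R1` (bounded below by 1), and the standard step-up q-values
#' are then rescaled by `m0/m`. When the first stage rejects nothing this
#' reduces to the plain linear step-up adjustment; when it rejects, the
#' adaptive q-values are uniformly no larger.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Nominal FDR level used for the first-stage null-count
#'   estimate (default 0.05).
#' @return Numeric vector of q-values, same length and order as `p`;
#'   monotone in `p` and bounded by \[0, 1\].
#' @examples
#' adjust_fdr(c(0.001, 0.01, 0.2, 0.8))
#' @export
adjust_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  bh <- stats::p.adjust(p, method = "BH")
  r1 <- sum(bh <= alpha / (1 + alpha))
  m0 <- max(1L, m - r1)
  pmin(1, bh * m0 / m)
}

#' Broad-sense repeatability of entry means
#'
#' Entry-mean repeatability within one entry class, from the expected mean
#' squares of the two-way genotype x environment ANOVA (replications
#' nested in environments):
#' `R = sigma2_G / (sigma2_G + sigma2_GE / nE + sigma2_e / (nE * nR))`,
#' with variance components estimated by the method of moments
#' (`sigma2_e` = residual MS; `sigma2_GE = (MS_GxE - MS_e)/nR`;
#' `sigma2_G = (MS_G - MS_GxE)/(nE nR)`) and negative component
#' estimates truncated at zero. For a selected (non-random) set of
#' entries this is a repeatability, not a heritability.
#'
#' @param data Data frame with one row per plot.
#' @param trait Trait column name.
#' @param genotype,env,rep Names of the genotype, environment and
#'   replication columns (defaults `"entry_id"`, `"env"`, `"rep"`).
#' @return A list with `R` (repeatability in \[0, 1\]), the three
#'   variance components, and `nE`, `nR`.
#' @export
repeatability <- function(data, trait, genotype = "entry_id",
                          env = "env", rep = "rep") {
  d <- data.frame(y = data[[trait]],
                  G = factor(data[[genotype]]),
                  E = factor(data[[env]]),
                  R = factor(paste(data[[env]], data[[rep]], sep = ".")))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  nE <- nlevels(droplevels(d$E))
  if (nE < 2L) stop("repeatability needs at least 2 environments")
  nR <- mean(table(d$G, d$E))   # average plots per genotype-environment cell
  if (nR < 2) stop("repeatability needs at least 2 replications")
  av <- stats::anova(stats::aov(y ~ E + R %in% E + G + G:E, data = d))
  ms <- av$`Mean Sq`
  rn <- rownames(av)
  ms_g <- ms[rn == "G"]
  ms_ge <- ms[rn == "E:G" | rn == "G:E"]
  ms_e <- ms[rn == "Residuals"]
  if (!is.finite(ms_e)) ms_e <- 0
  s2e <- max(0, ms_e)
  s2ge <- max(0, (ms_ge - s2e) / nR)
  s2g <- max(0, (ms_g - ms_ge) / (nE * nR))
  denom <- s2g + s2ge / nE + s2e / (nE * nR)
  R <- if (denom <= 0) 0 else s2g / denom
  list(R = R, sigma2_G = s2g, sigma2_GE = s2ge, sigma2_e = s2e,
       nE = nE, nR = nR)
}
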