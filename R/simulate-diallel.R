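#' Specification of a simulated diallel experiment
#'
#' Defines the design (parents, all unordered crosses, checks,
#' environments, replications) and the true fixed effects of a
#' generation-block diallel phenotype, matching the model fitted by
#' [fit_diallel()]: overall mean, environment effects, replication-
#' within-environment effects, entry-class (generation block) effects,
#' additive line effects per se `a_l`, general combining abilities `g_l`,
#' specific combining abilities `s_lm`, check effects `c_n`, and the
#' environment interactions with class, additive and check effects.
#'
#' Every effect family must satisfy the sum-to-zero restriction over its
#' index (for SCA: over the crosses involving each line), so the truth is
#' identifiable under the same constraints the model uses.
#'
#' @param parent_ids Character vector of parent line names (the study
#'   design uses 12).
#' @param check_ids Character vector of check entry names.
#' @param env_ids Character vector of environment names (study: 2 years).
#' @param reps_per_env Replications nested in each environment (study: 3).
#' @param mu Overall mean.
#' @param env,class_effect,a,g,check Named numeric vectors of true
#'   effects: `env` over `env_ids`; `class_effect` over
#'   `c("parent","F1","check")`; `a` and `g` over `parent_ids`; `check`
#'   over `check_ids`. Each must sum to zero (within tolerance). Defaults
#'   are zeros.
#' @param s Named numeric vector of SCA effects over crosses named
#'   `"P1:P2"` (parents in `parent_ids` order); must satisfy, for every
#'   line, sum over its crosses = 0. Default zeros.
#' @param rep_effect Optional matrix `env x rep` of replication effects
#'   (rows sum to zero); default zeros.
#' @param env_class,env_a,env_check Optional interaction matrices
#'   (`env x class`, `env x parent`, `env x check`), each row and column
#'   family summing to zero; default zeros.
#' @param residual_sd Gaussian residual standard deviation (>= 0).
#' @param rng_seed Integer seed for the residuals.
#' @param trait Trait name attached to the simulated column.
#' @return A validated list of class `diallel_sim_spec`.
#' @export
diallel_sim_spec <- function(parent_ids = paste0("P", sprintf("%02d", 1:12)),
                             check_ids = paste0("CHK", 1:6),
                             env_ids = c("E1", "E2"),
                             reps_per_env = 3L,
                             mu = 0,
                             env = NULL, class_effect = NULL,
                             a = NULL, g = NULL, s = NULL, check = NULL,
                             rep_effect = NULL, env_class = NULL,
                             env_a = NULL, env_check = NULL,
                             residual_sd = 0, rng_seed = 1L,
                             trait = "y") {
  classes <- c("parent", "F1", "check")
  crosses <- cross_names(parent_ids)
  zero <- function(nm) stats::setNames(numeric(length(nm)), nm)
  fill <- function(x, nm, what) {
    if (is.null(x)) return(zero(nm))
    if (is.null(names(x)) && length(x) == length(nm)) names(x) <- nm
    if (!setequal(names(x), nm)) stop(what, " names must be exactly {",
                                      paste(nm, collapse = ", "), "}")
    x[nm]
  }
  zmat <- function(x, rn, cn, what) {
    if (is.null(x)) {
      x <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
    }
    if (!identical(sort(rownames(x)), sort(rn)) ||
        !identical(sort(colnames(x)), sort(cn))) {
      stop(what, " must have rows {", paste(rn, collapse = ","),
           "} and columns {", paste(cn, collapse = ","), "}")
    }
    x[rn, cn, drop = FALSE]
  }
  spec <- list(parent_ids = parent_ids, check_ids = check_ids,
               env_ids = env_ids, reps_per_env = as.integer(reps_per_env),
               crosses = crosses, mu = mu,
               env = fill(env, env_ids, "env"),
               class_effect = fill(class_effect, classes, "class_effect"),
               a = fill(a, parent_ids, "a"),
               g = fill(g, parent_ids, "g"),
               s = fill(s, crosses, "s"),
               check = fill(check, check_ids, "check"),
               rep_effect = zmat(rep_effect, env_ids,
                                 paste0("R", seq_len(reps_per_env)),
                                 "rep_effect"),
               env_class = zmat(env_class, env_ids, classes, "env_class"),
               env_a = zmat(env_a, env_ids, parent_ids, "env_a"),
               env_check = zmat(env_check, env_ids, check_ids, "env_check"),
               residual_sd = residual_sd,
               rng_seed = as.integer(rng_seed), trait = trait)
  stopifnot(residual_sd >= 0, length(parent_ids) >= 2L,
            length(env_ids) >= 1L, reps_per_env >= 1L)
  check_sum_zero(spec)
  class(spec) <- "diallel_sim_spec"
  spec
}

cross_names <- function(parent_ids) {
  p <- length(parent_ids)
  unlist(lapply(seq_len(p - 1L), function(l) {
    vapply((l + 1L):p, function(m) {
      paste(parent_ids[l], parent_ids[m], sep = ":")
    }, character(1))
  }))
}

check_sum_zero <- function(spec, tol = 1e-8) {
  chk <- function(x, what) {
    if (abs(sum(x)) > tol * max(1, max(abs(x)))) {
      stop(what, " effects must sum to zero (got sum ", sum(x), ")")
    }
  }
  chk(spec$env, "env"); chk(spec$class_effect, "class_effect")
  chk(spec$a, "a"); chk(spec$g, "g"); chk(spec$check, "check")
  # SCA: sum over the crosses containing each line must vanish
  for (l in spec$parent_ids) {
    inl <- grepl(paste0("(^|:)", l, "(:|$)"), names(spec$s), perl = TRUE)
    chk(spec$s[inl], paste0("s (crosses of ", l, ")"))
  }
  for (rn in rownames(spec$rep_effect)) {
    chk(spec$rep_effect[rn, ], paste0("rep_effect[", rn, ",]"))
  }
  for (m in c("env_class", "env_a", "env_check")) {
    M <- spec[[m]]
    for (i in seq_len(nrow(M))) chk(M[i, ], paste0(m, " row ", i))
    for (j in seq_len(ncol(M))) chk(M[, j], paste0(m, " col ", j))
  }
  invisible(TRUE)
}

#' Simulate a diallel phenotype table from known effects
#'
#' Generates one plot-mean record per environment x replication x entry
#' (parents, all unordered F1 crosses, checks). Entry classes receive the
#' design coefficients of the generation-block diallel model exactly:
#' parent rows carry their own additive effect with weight 1; cross rows
#' carry half of each parent's additive effect plus both GCAs and the
#' cross SCA; check rows carry only the check effect. Gaussian residual
#' noise with `residual_sd` is added, seeded by `rng_seed` (no global RNG
#' state is disturbed).
#'
#' @param spec A [diallel_sim_spec()].
#' @return A data frame with columns `env`, `rep`, `entry_class`
#'   (`parent`/`F1`/`check`), `parent1`, `parent2` (NA for checks),
#'   `check_id` (NA otherwise), `entry_id`, and the trait column named
#'   `spec$trait`.
#' @examples
#' spec <- diallel_sim_spec(parent_ids = c("A", "B", "C"),
#'                          check_ids = "CHK1", mu = 10)
#' head(simulate_diallel_dataset(spec))
#' @export
simulate_diallel_dataset <- function(spec) {
  stopifnot(inherits(spec, "diallel_sim_spec"))
  check_sum_zero(spec)
  entries <- rbind(
    data.frame(entry_class = "parent", parent1 = spec$parent_ids,
               parent2 = NA_character_, check_id = NA_character_),
    do.call(rbind, lapply(strsplit(spec$crosses, ":", fixed = TRUE),
                          function(pr) data.frame(entry_class = "F1",
                                                  parent1 = pr[1L],
                                                  parent2 = pr[2L],
                                                  check_id = NA_character_))),
    if (length(spec$check_ids))
      data.frame(entry_class = "check", parent1 = NA_character_,
                 parent2 = NA_character_, check_id = spec$check_ids)
  )
  entries$entry_id <- ifelse(entries$entry_class == "parent",
                             entries$parent1,
                      ifelse(entries$entry_class == "F1",
                             paste(entries$parent1, entries$parent2,
                                   sep = ":"),
                             entries$check_id))
  design <- expand.grid(env = spec$env_ids,
                        rep = paste0("R", seq_len(spec$reps_per_env)),
                        idx = seq_len(nrow(entries)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- cbind(design[c("env", "rep")], entries[design$idx, , drop = FALSE])
  rownames(out) <- NULL

  gval <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    cls <- out$entry_class[i]
    if (cls == "parent") {
      gval[i] <- spec$a[out$parent1[i]] +
        spec$env_a[out$env[i], out$parent1[i]]
    } else if (cls == "F1") {
      l <- out$parent1[i]; m <- out$parent2[i]
      gval[i] <- 0.5 * (spec$a[l] + spec$a[m]) +
        spec$g[l] + spec$g[m] + spec$s[paste(l, m, sep = ":")] +
        0.5 * (spec$env_a[out$env[i], l] + spec$env_a[out$env[i], m])
    } else {
      gval[i] <- spec$check[out$check_id[i]] +
        spec$env_check[out$env[i], out$check_id[i]]
    }
  }
  y <- spec$mu + spec$env[out$env] + spec$rep_effect[cbind(out$env, out$rep)] +
    spec$class_effect[out$entry_class] +
    spec$env_class[cbind(out$env, out$entry_class)] + gval
  if (spec$residual_sd > 0) {
    noise <- with_seed(spec$rng_seed,
                       stats::rnorm(length(y), 0, spec$residual_sd))
    y <- y + noise
  }
  out[[spec$trait]] <- unname(y)
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Realistic per-trait simulation settings for the four root traits
#'
#' Returns a [diallel_sim_spec()] whose magnitudes emulate a two-year,
#' three-replicate field evaluation of 12 elite parents, their 66 F1
#' crosses and 6 checks: trait means, environment differences, mid-parent
#' heterosis encoded in the entry-class effects, additive line effects of
#' realistic spread, modest GCA/SCA, and residual noise on the scale of
#' the plot-mean repeatabilities reported for such trials.
#'
#' @param trait One of `"FD"`, `"FA"`, `"RA"`, `"SD"` (fractal dimension,
#'   log-scale fractal abundance, root angle in degrees, stalk diameter in
#'   pixels).
#' @param rng_seed Seed used both to draw the fixed effect vectors (so the
#'   truth varies across seeds but is always recorded in the returned
#'   spec) and for the residual noise.
#' @return A `diallel_sim_spec`.
#' @export
root_trait_sim_spec <- function(trait = c("FD", "FA", "RA", "SD"),
                                rng_seed = 1L) {
  trait <- match.arg(trait)
  # mu, env difference (E1 - E2), heterosis (F1 - parent class mean),
  # sd(a), sd(g), sd(s), residual sd
  cfg <- switch(trait,
    FD = list(mu = 1.78, envd = -0.074, het = 0.038, sa = 0.03,
              sg = 0.005, ss = 0.01, se = 0.022),
    FA = list(mu = 11.2, envd = 0.15, het = 0.31, sa = 0.25,
              sg = 0.04, ss = 0.08, se = 0.18),
    RA = list(mu = 70, envd = 0.1, het = 14.5, sa = 8, sg = 1.2,
              ss = 3, se = 7),
    SD = list(mu = 118, envd = -32.6, het = 2.3, sa = 15, sg = 3,
              ss = 5, se = 23.9))
  parents <- c("B73", "MO17", "LH1", "LH82", "LH123HT", "PH207",
               "PHG35", "PHG39", "PHG47", "PHG84", "PHJ40", "PHZ51")
  checks <- paste0("CHK", 1:6)
  with_seed(rng_seed + 1000L, {
    center <- function(x) x - mean(x)
    a <- center(stats::rnorm(12, 0, cfg$sa))
    g <- center(stats::rnorm(12, 0, cfg$sg))
    names(a) <- names(g) <- parents
    s_raw <- stats::rnorm(66, 0, cfg$ss)
    names(s_raw) <- cross_names(parents)
    s <- project_sca_sum_zero(s_raw, parents)
    chk <- center(stats::rnorm(6, 0, cfg$sa / 2))
    names(chk) <- checks
    cls <- c(parent = -cfg$het / 2, F1 = cfg$het / 2, check = 0)
    cls <- cls - mean(cls)
    diallel_sim_spec(parent_ids = parents, check_ids = checks,
                     env_ids = c("E1", "E2"), reps_per_env = 3L,
                     mu = cfg$mu,
                     env = c(E1 = cfg$envd / 2, E2 = -cfg$envd / 2),
                     class_effect = cls, a = a, g = g, s = s, check = chk,
                     residual_sd = cfg$se, rng_seed = rng_seed,
                     trait = trait)
  })
}

# Orthogonal projection of a raw SCA vector onto the subspace where, for
# every line, the sum over its crosses vanishes.
project_sca_sum_zero <- function(s, parent_ids) {
  A <- sca_constraint_matrix(parent_ids)
  # projection onto null space of A: s - A' (A A')^-1 A s
  s_proj <- s - drop(crossprod(A, solve(tcrossprod(A), A %*% s)))
  stats::setNames(s_proj, names(s))
}

sca_constraint_matrix <- function(parent_ids) {
  crosses <- cross_names(parent_ids)
  A <- matrix(0, length(parent_ids), length(crosses),
              dimnames = list(parent_ids, crosses))
  for (cr in crosses) {
    pr <- strsplit(cr, ":", fixed = TRUE)[[1L]]
    A[pr[1L], cr] <- 1
    A[pr[2L], cr] <- 1
  }
  A
}

#' Simulate the four root traits on one shared design
#'
#' Convenience wrapper calling [root_trait_sim_spec()] +
#' [simulate_diallel_dataset()] for FD, FA, RA and SD and merging the
#' results into one phenotype table (shared design keys, one column per
#' trait).
#'
#' @param rng_seed Integer seed; trait t uses `rng_seed + offset(t)`.
#' @return A data frame with design keys and the four trait columns, plus
#'   an attribute `specs` holding the per-trait true-effect specs.
#' @export
simulate_root_traits <- function(rng_seed = 1L) {
  traits <- c("FD", "FA", "RA", "SD")
  specs <- lapply(seq_along(traits), function(i) {
    root_trait_sim_spec(traits[i], rng_seed = rng_seed + 17L * i)
  })
  names(specs) <- traits
  tabs <- lapply(specs, simulate_diallel_dataset)
  out <- tabs[[1L]]
  for (i in 2:length(tabs)) out[[traits[i]]] <- tabs[[i]][[traits[i]]]
  attr(out, "specs") <- specs
  out
}
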