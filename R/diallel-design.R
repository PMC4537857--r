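#' Diallel design description
#'
#' The fixed design of a generation-block diallel trial: a set of parent
#' lines crossed in all unordered pairs (no reciprocals), commercial check
#' entries, environments, and replications nested in environments. With
#' `p` parents there are `p(p-1)/2` crosses; for the 12-parent study
#' design that is 66.
#'
#' @param parent_ids Character vector of parent names (>= 2).
#' @param check_ids Character vector of check names (may be empty).
#' @param env_ids Character vector of environments (>= 1).
#' @param reps_per_env Integer replications per environment.
#' @return A list of class `diallel_spec` with the ids and the enumerated
#'   `crosses` (`"P1:P2"` naming, parents in `parent_ids` order).
#' @export
diallel_spec <- function(parent_ids, check_ids = character(0),
                         env_ids = c("E1", "E2"), reps_per_env = 3L) {
  stopifnot(length(parent_ids) >= 2L, !anyDuplicated(parent_ids),
            !anyDuplicated(check_ids), length(env_ids) >= 1L,
            reps_per_env >= 1L)
  structure(list(parent_ids = parent_ids, check_ids = check_ids,
                 env_ids = env_ids,
                 reps_per_env = as.integer(reps_per_env),
                 crosses = cross_names(parent_ids)),
            class = "diallel_spec")
}

# Sum-to-zero contrast basis for a factor with levels `lev`:
# length(lev) x (length(lev)-1), columns = free levels, last level = -1 row.
sum_zero_basis <- function(lev) {
  k <- length(lev)
  B <- rbind(diag(k - 1L), rep(-1, k - 1L))
  dimnames(B) <- list(lev, lev[-k])
  B
}

#' Build the generation-block diallel design matrix
#'
#' Constructs the fixed-effects design matrix of the modified
#' generation-block diallel model for a set of plot records. For each
#' trait plot mean the linear predictor contains: intercept; environment
#' main effects; replications nested in environments; entry-class
#' (generation block) effects for the parent, F1 and check blocks;
#' additive line effects per se `a_l`, entering with weight 1 for a
#' parent's own plot and weight 0.5 for each parent of a cross; general
#' combining abilities `g_l` and specific combining abilities `s_lm`,
#' entering with weight 1 on cross plots only; check-entry effects on
#' check plots only; and the environment interactions with entry class,
#' with the additive effects (line x environment), and with the checks.
#'
#' All effect families carry sum-to-zero restrictions to ensure
#' estimability; for the SCA family the restriction is that, for every
#' line, its cross effects sum to zero, leaving `p(p-3)/2` free columns.
#' For 12 parents the genetic part therefore has 11 (additive) + 11 (GCA)
#' + 54 (SCA) = 76 free columns.
#'
#' @param spec A [diallel_spec()].
#' @param keys Data frame with one row per plot and columns `env`, `rep`,
#'   `entry_class` (`"parent"`, `"F1"`, `"check"`), `parent1`, `parent2`,
#'   `check_id`.
#' @return A list of class `diallel_design` with elements `X` (numeric
#'   design matrix, named columns), `terms` (named list mapping model
#'   terms to their column indices), `bases` (the per-family recovery
#'   bases, used to map fitted free coefficients back to full effect
#'   vectors), `spec`, and `keys`.
#' @export
build_design <- function(spec, keys) {
  stopifnot(inherits(spec, "diallel_spec"))
  need <- c("env", "rep", "entry_class", "parent1", "parent2", "check_id")
  if (!all(need %in% names(keys))) {
    stop("keys must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(keys)
  classes <- c("parent", "F1", "check")
  if (!all(keys$entry_class %in% classes)) {
    stop("unknown entry_class: ",
         paste(setdiff(unique(keys$entry_class), classes), collapse = ", "))
  }
  bad_par <- setdiff(stats::na.omit(c(keys$parent1, keys$parent2)),
                     spec$parent_ids)
  if (length(bad_par)) stop("unknown parent id: ",
                            paste(bad_par, collapse = ", "))
  bad_chk <- setdiff(stats::na.omit(keys$check_id), spec$check_ids)
  if (length(bad_chk)) stop("unknown check id: ",
                            paste(bad_chk, collapse = ", "))
  is_f1 <- keys$entry_class == "F1"
  if (any(is_f1)) {
    l_idx <- match(keys$parent1[is_f1], spec$parent_ids)
    m_idx <- match(keys$parent2[is_f1], spec$parent_ids)
    if (any(l_idx >= m_idx)) {
      stop("reciprocal or self cross present: crosses must be unordered ",
           "pairs with parent1 before parent2 in spec order")
    }
  }

  # raw incidence (full, redundant) coefficient matrices per family
  p <- length(spec$parent_ids)
  Z_env <- outer(keys$env, spec$env_ids, `==`) * 1
  colnames(Z_env) <- spec$env_ids
  rep_ids <- sort(unique(keys$rep))
  Z_class <- outer(keys$entry_class, classes, `==`) * 1
  colnames(Z_class) <- classes

  Z_a <- matrix(0, n, p, dimnames = list(NULL, spec$parent_ids))
  Z_g <- matrix(0, n, p, dimnames = list(NULL, spec$parent_ids))
  Z_s <- matrix(0, n, length(spec$crosses),
                dimnames = list(NULL, spec$crosses))
  for (i in seq_len(n)) {
    cls <- keys$entry_class[i]
    if (cls == "parent") {
      Z_a[i, keys$parent1[i]] <- 1
    } else if (cls == "F1") {
      Z_a[i, keys$parent1[i]] <- 0.5
      Z_a[i, keys$parent2[i]] <- 0.5
      Z_g[i, keys$parent1[i]] <- 1
      Z_g[i, keys$parent2[i]] <- 1
      Z_s[i, paste(keys$parent1[i], keys$parent2[i], sep = ":")] <- 1
    }
  }
  nchk <- length(spec$check_ids)
  Z_c <- matrix(0, n, nchk, dimnames = list(NULL, spec$check_ids))
  ischk <- keys$entry_class == "check"
  if (nchk) Z_c[cbind(which(ischk), match(keys$check_id[ischk],
                                          spec$check_ids))] <- 1

  # sum-to-zero reductions
  B_env <- sum_zero_basis(spec$env_ids)
  B_class <- sum_zero_basis(classes)
  B_par <- sum_zero_basis(spec$parent_ids)
  B_sca <- sca_null_basis(spec$parent_ids)
  B_chk <- if (nchk >= 2L) sum_zero_basis(spec$check_ids) else
    matrix(0, nchk, 0)

  named <- function(M, prefix) {
    if (ncol(M)) colnames(M) <- paste0(prefix, colnames(M))
    M
  }
  X_env <- named(Z_env %*% B_env, "env_")
  # replications nested in env: per env, sum-to-zero over that env's reps
  X_rep <- NULL
  for (e in spec$env_ids) {
    reps_e <- sort(unique(keys$rep[keys$env == e]))
    if (length(reps_e) >= 2L) {
      Zr <- outer(keys$rep, reps_e, `==`) * (keys$env == e)
      Xr <- Zr %*% sum_zero_basis(reps_e)
      colnames(Xr) <- paste0("rep_", e, ".", reps_e[-length(reps_e)])
      X_rep <- cbind(X_rep, Xr)
    }
  }
  if (is.null(X_rep)) X_rep <- matrix(0, n, 0)
  X_class <- named(Z_class %*% B_class, "class_")
  X_a <- named(Z_a %*% B_par, "a_")
  X_g <- named(Z_g %*% B_par, "g_")
  X_s <- Z_s %*% B_sca
  colnames(X_s) <- paste0("sca_", seq_len(ncol(X_s)))
  X_c <- named(Z_c %*% B_chk, "check_")

  inter <- function(A, B, prefix) {
    if (!ncol(A) || !ncol(B)) return(matrix(0, n, 0))
    M <- do.call(cbind, lapply(seq_len(ncol(A)), function(j) {
      out <- B * A[, j]
      colnames(out) <- paste0(prefix, colnames(A)[j], ":", colnames(B))
      out
    }))
    M
  }
  X_eb <- inter(X_env, X_class, "x_")
  X_rb <- inter(X_rep, X_class, "x_")
  X_d <- inter(X_env, X_a, "x_")
  X_ec <- inter(X_env, X_c, "x_")

  parts <- list(`(Intercept)` = matrix(1, n, 1,
                                       dimnames = list(NULL, "(Intercept)")),
                env = X_env, rep_in_env = X_rep, entry_class = X_class,
                lines_per_se = X_a, gca = X_g, sca = X_s, checks = X_c,
                env_x_class = X_eb, rep_x_class = X_rb,
                line_x_env = X_d, check_x_env = X_ec)
  X <- do.call(cbind, parts)
  idx <- split(seq_len(ncol(X)),
               rep(names(parts), vapply(parts, ncol, integer(1))))
  idx <- idx[names(parts)[vapply(parts, ncol, integer(1)) > 0L]]
  structure(list(X = X, terms = idx,
                 bases = list(env = B_env, class = B_class, parent = B_par,
                              sca = B_sca, check = B_chk),
                 spec = spec, keys = keys),
            class = "diallel_design")
}

# Basis of the SCA subspace: columns span {s : for every line l,
# sum of s over crosses containing l = 0}; dimension p(p-3)/2.
sca_null_basis <- function(parent_ids) {
  A <- sca_constraint_matrix(parent_ids)
  sv <- svd(A, nu = 0, nv = length(cross_names(parent_ids)))
  r <- sum(sv$d > max(dim(A)) * max(sv$d) * .Machine$double.eps)
  B <- sv$v[, (r + 1L):ncol(sv$v), drop = FALSE]
  rownames(B) <- cross_names(parent_ids)
  B
}

#' @export
print.diallel_design <- function(x, ...) {
  cat(sprintf("<diallel_design: %d plots x %d columns; terms: %s>\n",
              nrow(x$X), ncol(x$X),
              paste(names(x$terms), vapply(x$terms, length, integer(1)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
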