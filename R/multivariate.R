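#' Per-entry-class trait correlations
#'
#' Pairwise-complete Pearson correlations among trait columns, computed
#' within one entry class (or over all rows when `entry_class = NULL`),
#' with per-pair two-sided p-values from the usual t approximation.
#'
#' @param records Data frame of plot or entry records.
#' @param traits Character vector of trait columns.
#' @param entry_class Optional class label; rows are filtered on the
#'   `entry_class` column.
#' @return A list with `r` (correlation matrix, unit diagonal), `p`
#'   (p-value matrix, `NA` diagonal), and `n` (pairwise complete counts).
#' @export
class_correlations <- function(records, traits, entry_class = NULL) {
  if (!is.null(entry_class)) {
    records <- records[records$entry_class == entry_class, , drop = FALSE]
  }
  X <- as.matrix(records[, traits, drop = FALSE])
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    stop("constant trait: ", paste(traits[sds == 0], collapse = ", "))
  }
  k <- length(traits)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(traits, traits)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- stats::complete.cases(X[, c(i, j)])
    nij <- sum(ok)
    if (nij < 3L) stop("fewer than 3 complete pairs for ",
                       traits[i], " vs ", traits[j])
    rij <- stats::cor(X[ok, i], X[ok, j])
    tij <- rij * sqrt((nij - 2) / max(1e-300, 1 - rij^2))
    pij <- 2 * stats::pt(abs(tij), nij - 2, lower.tail = FALSE)
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
    n[i, j] <- n[j, i] <- nij
  }
  list(r = r, p = p, n = n)
}

#' Maturity adjustment of a trait
#'
#' Removes the linear association of a trait with a maturity covariate
#' (days to silking): the adjusted values are the residuals of a simple
#' linear regression of the trait on the covariate, re-centred at the
#' trait mean, so later-flowering entries are not conflated with
#' larger-rooted ones in multivariate summaries.
#'
#' @param values Numeric trait vector.
#' @param covariate Numeric maturity covariate, same length; must not be
#'   constant.
#' @return A list with `adjusted` (numeric vector), `slope`, and
#'   `slope_se`.
#' @export
maturity_adjust <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  ok <- stats::complete.cases(values, covariate)
  if (stats::sd(covariate[ok]) == 0) stop("constant maturity covariate")
  fit <- stats::lm(values ~ covariate, subset = ok)
  adj <- rep(NA_real_, length(values))
  adj[ok] <- stats::residuals(fit) + mean(values[ok])
  sm <- summary(fit)$coefficients
  list(adjusted = adj, slope = unname(sm["covariate", "Estimate"]),
       slope_se = unname(sm["covariate", "Std. Error"]))
}

#' Column standardization to Z scores
#'
#' Centres each column to mean 0 and scales to unit standard deviation.
#'
#' @param x Numeric matrix or data frame of traits.
#' @return Numeric matrix of the same shape.
#' @export
zscore <- function(x) {
  X <- as.matrix(x)
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    stop("zero-variance column: ",
         paste(colnames(X)[which(sds == 0)], collapse = ", "))
  }
  scale(X)[, , drop = FALSE]
}

#' Principal components of the trait correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of the traits
#' (equivalently, PCA of the Z-scored data). Eigenvalues sum to the
#' number of traits; the variance explained by a component is its
#' eigenvalue over that sum. Loading signs follow the convention that
#' each component's largest-magnitude loading is positive.
#'
#' @param x Numeric matrix or data frame, entries x traits (>= 3 entries,
#'   >= 2 traits). Pairwise-complete correlations are used.
#' @return A list of class `pca_correlation` with `eigenvalues`,
#'   `loadings` (traits x components, orthonormal), `variance_explained`
#'   (fractions), and `scores` (when `x` has no missing values).
#' @export
pca_correlation <- function(x) {
  X <- as.matrix(x)
  if (ncol(X) < 2L || nrow(X) < 3L) {
    stop("need at least 2 traits and 3 entries")
  }
  R <- stats::cor(X, use = "pairwise.complete.obs")
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(0, eg$values)        # rank deficiency -> zero eigenvalues
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(X), paste0("PC", seq_len(ncol(vecs))))
  scores <- if (!anyNA(X)) {
    zscore(X) %*% vecs
  } else NULL
  structure(list(eigenvalues = vals,
                 loadings = vecs,
                 variance_explained = vals / sum(vals),
                 scores = scores),
            class = "pca_correlation")
}

#' @export
print.pca_correlation <- function(x, ...) {
  cat("<pca_correlation>\n eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
      "\n variance explained (%):",
      paste(sprintf("%.1f", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Hierarchical clustering of entries on phenotypic distance
#'
#' Agglomerative clustering of (typically Z-scored) entries on Euclidean
#' phenotypic distances, Ward linkage by default. Rows are ordered by
#' entry id before clustering so the result is independent of input
#' order.
#'
#' @param z Numeric matrix, entries x traits; `rownames(z)` are entry
#'   ids (defaults to row numbers).
#' @param k Number of clusters to cut (1 <= k <= entries).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return A list of class `cluster_result` with `tree` (hclust),
#'   `labels` (named cluster id per entry, in the input row order), and
#'   `cluster_means` (cluster x trait means).
#' @export
hcluster <- function(z, k, method = "ward.D2") {
  Z <- as.matrix(z)
  if (is.null(rownames(Z))) rownames(Z) <- sprintf("entry%04d", seq_len(nrow(Z)))
  if (k > nrow(Z)) stop("k (", k, ") exceeds the number of entries (",
                        nrow(Z), ")")
  ord <- order(rownames(Z))
  Zo <- Z[ord, , drop = FALSE]
  tree <- stats::hclust(stats::dist(Zo, method = "euclidean"),
                        method = method)
  lab_o <- stats::cutree(tree, k = k)
  labels <- lab_o[match(rownames(Z), rownames(Zo))]
  names(labels) <- rownames(Z)
  cm <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    colMeans(Z[labels == cl, , drop = FALSE])
  }))
  rownames(cm) <- paste0("cluster", sort(unique(labels)))
  structure(list(tree = tree, labels = labels, cluster_means = cm, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d entries in %d clusters (sizes %s)>\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}
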