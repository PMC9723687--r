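#' Pairwise community dissimilarity matrix
#'
#' Bray-Curtis or (binary) Jaccard dissimilarities between samples, via
#' [vegan::vegdist()].
#'
#' @param table `feature_table` or count matrix (taxa x samples).
#' @param method `"bray"` or `"jaccard"`.
#' @return symmetric matrix with a `metric` attribute.
#' @export
distance_matrix <- function(table, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  m <- ft_counts(table)
  d <- as.matrix(vegan::vegdist(t(m), method = method,
                                binary = method == "jaccard"))
  attr(d, "metric") <- method
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres \eqn{-\tfrac12 D^2} and eigendecomposes it. Axes are
#' ordered by eigenvalue; negative eigenvalues (non-Euclidean input) are
#' reported, not dropped, and axis percentages are taken relative to the
#' sum of positive eigenvalues only.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return list with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, sorted decreasing) and `percent_explained`
#'   (per positive axis).
#' @export
pcoa_ordination <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  n <- nrow(D)
  if (n < 2) stop("need at least two samples")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  vals <- e$values
  vals[abs(vals) < 1e-12 * max(1, abs(vals[1]))] <- 0
  pos <- which(vals > 0)
  coords <- if (length(pos))
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]),
                                            length(pos))
  else matrix(0, n, 1)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pct <- if (length(pos)) 100 * vals[pos] / sum(vals[pos]) else 0
  list(coordinates = coords, eigenvalues = vals, percent_explained = pct)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix (via [vegan::adonis2()]), with the add-one permutation p-value
#' convention `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups factor-like vector of group labels, one per sample; at
#'   least two groups, each non-empty.
#' @param n_perm number of random permutations (9999 by convention).
#' @param seed integer seed.
#' @return list with `f`, `r_squared`, `p_value`, `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 9999, seed = NULL) {
  D <- as.matrix(D)
  groups <- as.factor(groups)
  if (length(groups) != nrow(D)) stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(g = droplevels(groups))
  fit <- vegan::adonis2(stats::as.dist(D) ~ g, data = df,
                        permutations = n_perm)
  list(f = fit$F[1], r_squared = fit$R2[1], p_value = fit$`Pr(>F)`[1],
       n_perm = n_perm)
}
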