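#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Abundance-weighted phylogenetic turnover between two communities:
#' \deqn{\beta MNTD = 0.5\left[\sum_i f_{ik}\,\min_j \Delta_{i_k j_m} +
#'   \sum_i f_{im}\,\min_j \Delta_{i_m j_k}\right]}
#' where \eqn{f_{ik}} is the relative abundance of taxon i in community k
#' and \eqn{\Delta} the patristic distance to the closest taxon in the other
#' community. Symmetric in its two communities; comparing a community with
#' itself gives 0.
#'
#' @param x,y named non-negative abundance vectors (counts or relative
#'   abundances); names must appear in `D`. Each is renormalized to sum to 1
#'   over its positive entries.
#' @param D cophenetic distance matrix covering all named taxa (see
#'   [cophenetic_matrix()]).
#' @return betaMNTD in tree branch-length units.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
#' D <- cophenetic_matrix(tr)
#' beta_mntd(c(A = 1, B = 1), c(C = 1, D = 1), D) # 6
beta_mntd <- function(x, y, D) {
  x <- x[x > 0]; y <- y[y > 0]
  if (!length(x) || !length(y)) stop("empty community in beta_mntd")
  if (is.null(names(x)) || is.null(names(y))) stop("abundances must be named")
  miss <- setdiff(c(names(x), names(y)), rownames(D))
  if (length(miss)) stop("taxa absent from D: ", paste(miss, collapse = ", "))
  fx <- x / sum(x); fy <- y / sum(y)
  dxy <- D[names(x), names(y), drop = FALSE]
  0.5 * (sum(fx * apply(dxy, 1, min)) + sum(fy * apply(dxy, 2, min)))
}

#' All-pairs betaMNTD matrix
#'
#' @param table `feature_table` or count matrix (taxa x samples).
#' @param D cophenetic matrix covering the table's taxa.
#' @param weighted abundance-weighted (default) or presence/absence (each
#'   present taxon gets equal weight).
#' @return symmetric sample-by-sample matrix of betaMNTD values (0 diagonal).
#' @export
beta_mntd_matrix <- function(table, D, weighted = TRUE) {
  m <- ft_counts(table)
  if (!all(rownames(m) %in% rownames(D)))
    stop("cophenetic matrix does not cover all table taxa")
  D <- D[rownames(m), rownames(m), drop = FALSE]
  f <- community_weights(m, weighted)
  out <- cpp_bmntd(f, D)
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# internal: per-sample weights summing to 1 over present taxa
community_weights <- function(m, weighted) {
  if (weighted) {
    relative_abundance(m)
  } else {
    pres <- (m > 0) * 1
    relative_abundance(pres)
  }
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardizes observed betaMNTD against a null distribution obtained by
#' shuffling taxa among the tips of the phylogeny:
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD_{null}}) /
#'   sd(\beta MNTD_{null})}
#' One tip permutation is drawn per null replicate and shared across all
#' sample pairs. `betaNTI < -2` signals homogeneous selection (less
#' turnover than expected), `betaNTI > +2` variable selection.
#'
#' @param table `feature_table` or count matrix (taxa x samples).
#' @param tree rooted `phylo` with branch lengths covering the table's taxa;
#'   alternatively supply a precomputed cophenetic matrix via `D`.
#' @param n_null number of tip-shuffling permutations (999 by convention).
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @param weighted abundance-weighted betaMNTD (default) or
#'   presence/absence.
#' @param prune restrict the shuffle to tips present in the analyzed table
#'   (default), preserving null richness/abundance structure; `FALSE`
#'   shuffles across the full tree.
#' @param D optional precomputed cophenetic matrix (overrides `tree`).
#' @return object of class `beta_nti`: list with symmetric matrices `bnti`,
#'   `bmntd_obs`, `null_mean`, `null_sd` (diagonals `NA`) and `n_null`.
#' @export
beta_nti <- function(table, tree = NULL, n_null = 999, seed = NULL,
                     weighted = TRUE, prune = TRUE, D = NULL) {
  m <- ft_counts(table)
  if (ncol(m) < 2) stop("need at least two samples")
  if (any(colSums(m) == 0))
    stop("empty community (all-zero sample column): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  if (is.null(D)) {
    if (is.null(tree)) stop("supply `tree` or `D`")
    if (prune) tree <- ape::keep.tip(tree, intersect(tree$tip.label,
                                                     rownames(m)))
    D <- cophenetic_matrix(tree)
  }
  if (!all(rownames(m) %in% rownames(D)))
    stop("tree/cophenetic matrix does not cover all table taxa")
  pool <- rownames(D)
  # order the pool so table taxa come first; permutations act on the pool
  pool <- c(rownames(m), setdiff(pool, rownames(m)))
  D <- D[pool, pool, drop = FALSE]
  f <- community_weights(m, weighted)
  # pad weights for pool taxa absent from the table (weight 0 everywhere)
  if (length(pool) > nrow(f)) {
    pad <- matrix(0, length(pool) - nrow(f), ncol(f))
    f <- rbind(f, pad)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- cpp_bmntd(f, D)
  perms <- vapply(seq_len(n_null), function(i) sample.int(length(pool)),
                  integer(length(pool)))
  moments <- cpp_bmntd_null_moments(f, D, perms)
  null_mean <- moments$mean
  null_sd <- moments$sd
  degenerate <- is.finite(null_sd) & null_sd == 0
  diag(degenerate) <- FALSE
  if (any(degenerate)) {
    warning("null betaMNTD sd is 0 for ", sum(degenerate) / 2,
            " pair(s); betaNTI set to NaN")
  }
  bnti <- (obs - null_mean) / null_sd
  samples <- colnames(m)
  for (x in c("obs", "null_mean", "null_sd", "bnti")) {
    v <- get(x)
    dimnames(v) <- list(samples, samples)
    diag(v) <- NA_real_
    assign(x, v)
  }
  structure(list(bnti = bnti, bmntd_obs = obs, null_mean = null_mean,
                 null_sd = null_sd, n_null = n_null),
            class = "beta_nti")
}

#' @export
print.beta_nti <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  cat(sprintf("beta_nti: %d samples, %d nulls; betaNTI median %.2f [%.2f, %.2f]\n",
              ncol(x$bnti), x$n_null, median(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Long-format view of pairwise turnover results
#'
#' @param x a `beta_nti` object.
#' @param ... unused.
#' @return data.frame with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`.
#' @export
as.data.frame.beta_nti <- function(x, ...) {
  s <- colnames(x$bnti)
  idx <- which(upper.tri(x$bnti), arr.ind = TRUE)
  data.frame(sample_a = s[idx[, 1]], sample_b = s[idx[, 2]],
             bmntd_obs = x$bmntd_obs[idx], null_mean = x$null_mean[idx],
             null_sd = x$null_sd[idx], bnti = x$bnti[idx],
             stringsAsFactors = FALSE)
}
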