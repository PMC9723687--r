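# Shared fixtures and independent oracles.

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
}

# Independent naive double-loop betaMNTD oracle (never vectorized).
naive_bmntd <- function(x, y, D) {
  x <- x[x > 0]; y <- y[y > 0]
  fx <- x / sum(x); fy <- y / sum(y)
  s1 <- 0
  for (i in names(fx)) {
    best <- Inf
    for (j in names(fy)) best <- min(best, D[i, j])
    s1 <- s1 + fx[[i]] * best
  }
  s2 <- 0
  for (j in names(fy)) {
    best <- Inf
    for (i in names(fx)) best <- min(best, D[j, i])
    s2 <- s2 + fy[[j]] * best
  }
  0.5 * (s1 + s2)
}

# Small random community table on a random tree.
random_instance <- function(n_taxa, n_samples, seed, lambda = 3) {
  set.seed(seed)
  tree <- ape::rcoal(n_taxa)
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(tree$tip.label,
                              sprintf("S%02d", seq_len(n_samples))))
  # ensure no empty community
  for (s in seq_len(n_samples)) if (sum(m[, s]) == 0) m[1, s] <- 1
  list(tree = tree, m = m, D = ape::cophenetic.phylo(tree))
}

# Count table whose relative abundances are exact at the given depth.
counts_at_depth <- function(rel_counts, depth) {
  m <- rel_counts
  filler <- depth - colSums(m)
  stopifnot(all(filler >= 0))
  rbind(m, FILL = filler)
}
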