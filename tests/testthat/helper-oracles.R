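# Independent oracles used by the test suite. These deliberately avoid the
# code paths they check: the rmsd oracle uses Horn's quaternion closed form
# (no SVD), the tree oracle enumerates every 5-taxon topology and fits branch
# lengths by least squares.

# Minimal rmsd after proper rotation, via the largest eigenvalue of Horn's
# 4x4 quaternion key matrix.
quaternion_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  s <- crossprod(a0, b0)
  k <- matrix(c(
    s[1, 1] + s[2, 2] + s[3, 3], s[2, 3] - s[3, 2], s[3, 1] - s[1, 3], s[1, 2] - s[2, 1],
    s[2, 3] - s[3, 2], s[1, 1] - s[2, 2] - s[3, 3], s[1, 2] + s[2, 1], s[3, 1] + s[1, 3],
    s[3, 1] - s[1, 3], s[1, 2] + s[2, 1], -s[1, 1] + s[2, 2] - s[3, 3], s[2, 3] + s[3, 2],
    s[1, 2] - s[2, 1], s[3, 1] + s[1, 3], s[2, 3] + s[3, 2], -s[1, 1] - s[2, 2] + s[3, 3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE)$values)
  sqrt(max((sum(a0^2) + sum(b0^2) - 2 * lam) / nrow(a), 0))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# All 15 labeled unrooted binary topologies on 5 taxa, as Newick strings
# (choose the middle taxon, pair the rest into two cherries).
all_five_taxon_topologies <- function(taxa = c("A", "B", "C", "D", "E")) {
  out <- character(0)
  for (mid in seq_along(taxa)) {
    rest <- taxa[-mid]
    for (p in list(c(1, 2), c(1, 3), c(1, 4))) {
      ab <- rest[p]; cd <- rest[-p]
      out <- c(out, sprintf("((%s,%s),%s,(%s,%s));",
                            ab[1], ab[2], taxa[mid], cd[1], cd[2]))
    }
  }
  out
}

# Indicator design matrix: one row per taxon pair, one column per edge,
# 1 where the edge lies on the path between the pair.
tree_design_matrix <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  x <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (r in seq_len(nrow(pairs))) {
    np <- ape::nodepath(tree, pairs[r, 1], pairs[r, 2])
    for (s in seq_len(length(np) - 1)) {
      e <- match(paste(np[s], np[s + 1]), edge_key)
      if (is.na(e)) e <- match(paste(np[s + 1], np[s]), edge_key)
      x[r, e] <- 1
    }
  }
  list(x = x, pairs = pairs, tips = tips)
}

# Least-squares branch-length fit of a fixed topology to a distance matrix;
# returns the residual sum of squares and the fitted tree.
ls_fit_topology <- function(newick, d) {
  tree <- ape::read.tree(text = newick)
  dm <- tree_design_matrix(tree)
  y <- d[cbind(dm$tips[dm$pairs[, 1]], dm$tips[dm$pairs[, 2]])]
  fit <- stats::lm.fit(dm$x, y)
  tree$edge.length <- as.numeric(fit$coefficients)
  list(rss = sum(fit$residuals^2), tree = tree)
}

# Exhaustive oracle: the best-fitting of all 15 topologies.
best_topology_by_ls <- function(d) {
  taxa <- rownames(d)
  fits <- lapply(all_five_taxon_topologies(taxa), ls_fit_topology, d = d)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

# Small helper used across files: a quick default family.
make_test_family <- function(seed, n_taxa = 16, n_columns = 60, ...) {
  template <- make_template_structure(n_columns, seed * 7 + 1)
  cfg <- simulation_config(seed = seed, n_taxa = n_taxa,
                           n_columns = n_columns, ...)
  fam <- evolve_family(template, cfg)
  fam$template <- template
  fam
}
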