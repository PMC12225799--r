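#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the fraction of mismatching positions among columns where
#' both rows carry a residue. Pairs with no comparable columns are flagged as
#' missing, imputed with the maximum observed distance, and reported in the
#' `missing_pairs` attribute.
#'
#' @param msa character alignment matrix with at least 2 rows.
#' @return symmetric numeric matrix with zero diagonal, taxon dimnames, and
#'   attribute `missing_pairs` (data frame of imputed pairs, possibly empty).
#' @export
p_distance <- function(msa) {
  check_msa(msa)
  n <- nrow(msa)
  if (n < 2L) stop("need at least 2 rows")
  nongap <- msa != "-"
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  miss <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- nongap[i, ] & nongap[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        miss[[length(miss) + 1L]] <- data.frame(taxon_a = rownames(msa)[i],
                                                taxon_b = rownames(msa)[j])
      } else {
        d[i, j] <- d[j, i] <- sum(msa[i, comp] != msa[j, comp]) / nc
      }
    }
  }
  if (length(miss) > 0L) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- if (is.finite(mx)) mx else 0
  }
  attr(d, "missing_pairs") <- if (length(miss) > 0L) {
    do.call(rbind, miss)
  } else data.frame(taxon_a = character(0), taxon_b = character(0))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: iteratively join the pair minimizing the
#' Q-criterion `Q_ij = (n-2) d_ij - r_i - r_j`, with branch lengths from the
#' three-point formulas. Q ties are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is labeled by
#' its smallest member taxon). Negative branch lengths are clamped to zero
#' and the clamped deficit recorded in the `clamp_deficit` attribute.
#' Exact on additive (tree-metric) inputs.
#'
#' @param d symmetric distance matrix with taxon dimnames, >= 3 taxa.
#' @return unrooted `phylo` tree (basal trichotomy), with attribute
#'   `clamp_deficit` (total negative length removed).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  labels <- rownames(d)
  nwk <- labels                 # growing newick fragment per active cluster
  key <- labels                 # smallest member label, for tie-breaking
  clamp_deficit <- 0
  fmt <- function(x) sprintf("%.15g", x)
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(key[ij[1L]], key[ij[2L]])), collapse = "\r")
    })
    sel <- cand[order(pair_keys)[1L], ]
    i <- sel[[1L]]; j <- sel[[2L]]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { clamp_deficit <- clamp_deficit - bi; bi <- 0 }
    if (bj < 0) { clamp_deficit <- clamp_deficit - bj; bj <- 0 }
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    mkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], merged)
    key <- c(key[keep], mkey)
    n <- n - 1L
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bl <- c(b1, b2, b3)
  clamp_deficit <- clamp_deficit - sum(bl[bl < 0])
  bl[bl < 0] <- 0
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(bl[1]),
                 nwk[2], fmt(bl[2]), nwk[3], fmt(bl[3]))
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamp_deficit") <- clamp_deficit
  tree
}

#' Clade purity of a labeled tree under a k-way branch cut
#'
#' Cuts the tree into `k` groups by removing the `k - 1` longest internal
#' branches (deterministic tie-break on equal lengths) and scores
#' `purity = sum over groups of the plurality-label count / leaf count`.
#' A purity of 1 means every group is label-homogeneous. `k` equal to the
#' leaf count returns the singleton partition (purity 1) directly.
#'
#' @param tree a `phylo` tree.
#' @param labels named character vector mapping every tip label to a group
#'   label.
#' @param k number of groups, `2 <= k <=` leaf count.
#' @return purity in \[0, 1\].
#' @export
clade_purity <- function(tree, labels, k) {
  ntip <- ape::Ntip(tree)
  if (k < 2L || k > ntip) stop("k must be in 2..leaf count")
  if (!all(tree$tip.label %in% names(labels))) {
    stop("labels must cover every leaf")
  }
  if (k == ntip) return(1)
  nnode <- tree$Nnode
  internal <- which(tree$edge[, 2L] > ntip)
  if (k - 1L > length(internal)) {
    stop("fewer than k-1 internal branches (", length(internal), " available)")
  }
  len <- tree$edge.length[internal]
  ord <- order(-len, tree$edge[internal, 1L], tree$edge[internal, 2L])
  cut_edges <- internal[ord[seq_len(k - 1L)]]
  # union-find over all nodes using the surviving edges
  parent <- seq_len(ntip + nnode)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in setdiff(seq_len(nrow(tree$edge)), cut_edges)) {
    a <- find(tree$edge[e, 1L]); b <- find(tree$edge[e, 2L])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(ntip), find, integer(1))
  lab <- labels[tree$tip.label]
  plurality <- vapply(split(lab, comp), function(g) max(table(g)), numeric(1))
  sum(plurality) / ntip
}

#' Write / read Newick trees
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree` with an explicit
#' malformed-input contract: unbalanced parentheses are reported with the
#' character offset of the first imbalance.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("malformed Newick: unbalanced ')' at character ", i)
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars))
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: could not parse tree")
  tree
}
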