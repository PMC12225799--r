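test_that("p-distance counts mismatches over comparable columns", {
  m <- msa_from_strings(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL",
                          c = "AAAEFGHIKW"))
  d <- p_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.3)              # 3 of 10 differ
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_identical(nrow(attr(d, "missing_pairs")), 0L)
  expect_error(p_distance(m[1, , drop = FALSE]), "2 rows")
})

test_that("pairs with no comparable columns are flagged and imputed", {
  m <- msa_from_strings(c(a = "AC--", b = "--DE", c = "ACDE", d = "AWDE"))
  d <- p_distance(m)
  mp <- attr(d, "missing_pairs")
  expect_identical(nrow(mp), 1L)
  expect_setequal(c(mp$taxon_a, mp$taxon_b), c("a", "b"))
  expect_equal(d["a", "b"], max(d))           # imputed at the matrix maximum
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(d)
  expect_identical(ape::Ntip(tree), 3L)
  bl <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["a"]], 1)  # (3+4-5)/2
  expect_equal(bl[["b"]], 2)  # (3+5-4)/2
  expect_equal(bl[["c"]], 3)  # (4+5-3)/2
})

test_that("NJ recovers additive five-taxon trees exactly", {
  topos <- all_five_taxon_topologies()
  set.seed(99)
  for (nwk in topos[c(1, 6, 11)]) {   # one per middle-taxon family; the full
    gen <- ape::read.tree(text = nwk) # sweep runs in the acceptance suite
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 1)
    d <- ape::cophenetic.phylo(gen)
    d <- d[order(rownames(d)), order(colnames(d))]
    tree <- neighbor_joining(d)
    expect_equal(max(abs(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
                         - d)), 0, tolerance = 1e-9)
    skip_if_not_installed("phangorn")
    expect_equal(phangorn::RF.dist(tree, gen), 0)
  }
})

test_that("NJ agrees with ape::nj on noisy distances", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  fam <- make_test_family(61, n_taxa = 12)
  d <- p_distance(fam$msa)
  ours <- neighbor_joining(d)
  theirs <- ape::nj(d)
  expect_equal(phangorn::RF.dist(ours, ape::unroot(theirs)), 0)
})

test_that("equal distances resolve deterministically via the tie-break", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(ape::Ntip(t1), 5L)
  expect_true(all(t1$edge.length >= 0))
})

test_that("negative branch lengths are clamped and logged", {
  # a non-additive matrix known to drive one NJ branch negative
  d <- matrix(c(0, 2, 2, 9,
                2, 0, 1, 9,
                2, 1, 0, 2,
                9, 9, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- neighbor_joining(d)
  expect_true(all(tree$edge.length >= 0))
  expect_gt(attr(tree, "clamp_deficit"), 0)
})

test_that("clade purity scores labeled cuts correctly", {
  # two clean clades separated by one long internal branch
  tree <- ape::read.tree(text = "((a:1,b:1):5,(c:1,d:1):5,e:1);")
  labs <- c(a = "x", b = "x", c = "y", d = "y", e = "y")
  expect_equal(clade_purity(tree, labs, 2), 1)
  constant <- c(a = "z", b = "z", c = "z", d = "z", e = "z")
  expect_equal(clade_purity(tree, constant, 2), 1)
  expect_equal(clade_purity(tree, constant, 3), 1)
  # k = leaf count: singleton partition
  expect_equal(clade_purity(tree, labs, 5), 1)
  # mislabeled leaf caps purity below 1
  labs2 <- c(a = "x", b = "y", c = "y", d = "y", e = "y")
  expect_equal(clade_purity(tree, labs2, 2), 0.8)
  expect_error(clade_purity(tree, labs, 4), "internal branches")
  expect_error(clade_purity(tree, labs[-1], 2), "cover")
})

test_that("purity is monotone non-decreasing for nested cuts", {
  fam <- make_test_family(71, n_taxa = 24)
  tree <- neighbor_joining(p_distance(fam$msa))
  labs <- fam$truth$kingdom_label
  max_k <- sum(tree$edge[, 2] > ape::Ntip(tree)) + 1
  purities <- vapply(2:max_k, function(k) clade_purity(tree, labs, k),
                     numeric(1))
  expect_true(all(diff(purities) >= -1e-12))
  expect_true(all(purities >= 0 & purities <= 1))
})

test_that("newick IO round-trips and rejects malformed input with offsets", {
  tree <- ape::read.tree(text = "((a:0.123456789,b:0.2):0.0001,c:1e-4,(d:3,e:4):0.5);")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_identical(back$tip.label, tree$tip.label)
  o <- order(tree$edge[, 2]); ob <- order(back$edge[, 2])
  expect_equal(back$edge.length[ob], tree$edge.length[o], tolerance = 1e-9)

  writeLines("(A,B,C);", path)
  star <- read_newick(path)
  expect_identical(ape::Ntip(star), 3L)
  expect_identical(star$Nnode, 1L)

  writeLines("((A,B,C);", path)
  expect_error(read_newick(path), "character")
})
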