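test_that("template structure is deterministic, pseudo-symmetric and self-avoiding", {
  t1 <- make_template_structure(150, seed = 1)
  t2 <- make_template_structure(150, seed = 1)
  expect_identical(t1$xyz, t2$xyz)
  expect_identical(t1$aa, t2$aa)
  expect_false(identical(t1$xyz, make_template_structure(150, seed = 2)$xyz))

  # three lobes are near-copies of one another
  m <- 50
  for (k in 1:2) {
    sup <- kabsch(t1$xyz[1:m, ], t1$xyz[(k * m + 1):((k + 1) * m), ])
    expect_lt(sup$rmsd, 1.0)
  }
  # self-avoiding: non-consecutive atoms well separated
  d <- as.matrix(dist(t1$xyz))
  d[abs(row(d) - col(d)) <= 1] <- NA
  expect_gt(min(d, na.rm = TRUE), 2.0)
  # consecutive Calpha spacing stays in a plausible band (within-lobe)
  steps <- sqrt(rowSums(diff(t1$xyz[1:m, ])^2))
  expect_true(all(steps > 2.5 & steps < 5.5))
  expect_lt(abs(mean(steps) - 3.8), 0.5)
})

test_that("template preconditions are enforced", {
  expect_error(make_template_structure(8, 1), "invalid")
  expect_error(make_template_structure(10, 1), "invalid")
  expect_error(make_template_structure(-3, 1), "invalid")
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, core_positions = c(0, 5)), "1..n_columns")
  expect_error(simulation_config(seed = 1, core_positions = 200), "1..n_columns")
  expect_error(simulation_config(seed = 1, gap_rate = -0.1))
  cfg <- simulation_config(seed = 3)
  expect_length(cfg$core_positions, 7)
  expect_identical(cfg$core_positions,
                   simulation_config(seed = 3)$core_positions)
})

test_that("zero substitution rate gives identical sequences and zero rmsd", {
  template <- make_template_structure(60, 5)
  cfg <- simulation_config(seed = 5, n_taxa = 8, n_columns = 60,
                           substitution_rate = 0, gap_rate = 0)
  fam <- evolve_family(template, cfg)
  expect_true(all(fam$msa == fam$msa[rep(1, nrow(fam$msa)), ]))
  for (i in 2:8) {
    sup <- suppressWarnings(
      kabsch(fam$structures[[1]]$xyz, fam$structures[[i]]$xyz))
    expect_lt(sup$rmsd, 1e-10)
  }
})

test_that("planted core columns are invariant and gap-free by construction", {
  fam <- make_test_family(11, n_taxa = 24)
  core <- fam$truth$core_positions
  for (j in core) {
    expect_length(unique(fam$msa[, j]), 1)
    expect_false(any(fam$msa[, j] == "-"))
  }
  # labels cover all taxa
  expect_setequal(names(fam$truth$function_label), rownames(fam$msa))
  expect_setequal(names(fam$truth$kingdom_label), rownames(fam$msa))
  # structures drop exactly the gapped positions
  for (i in seq_len(4)) {
    s <- fam$structures[[i]]
    expect_identical(s$resno, unname(which(fam$msa[i, ] != "-")))
    expect_identical(s$aa, unname(fam$msa[i, fam$msa[i, ] != "-"]))
  }
})

test_that("function-mode core columns separate function groups", {
  fam <- make_test_family(13, n_taxa = 24, core_signal = "function")
  core <- fam$truth$core_positions
  fl <- fam$truth$function_label[rownames(fam$msa)]
  for (j in core) {
    # invariant within group, distinct across groups
    per_group <- split(fam$msa[, j], fl)
    expect_true(all(lengths(lapply(per_group, unique)) == 1))
    expect_length(unique(vapply(per_group, `[[`, character(1), 1)),
                  length(per_group))
  }
})

test_that("the family generator is seed-deterministic", {
  f1 <- make_test_family(21)
  f2 <- make_test_family(21)
  expect_identical(f1$msa, f2$msa)
  expect_identical(f1$structures[[5]]$xyz, f2$structures[[5]]$xyz)
  expect_identical(ape::write.tree(f1$truth$true_tree),
                   ape::write.tree(f2$truth$true_tree))
  expect_false(identical(f1$msa, make_test_family(22)$msa))
})

test_that("pairwise rmsd and identity are inversely coupled", {
  for (s in 1:3) {
    fam <- make_test_family(30 + s, n_taxa = 20, n_columns = 90)
    pairs <- rmsd_identity_pairs(fam$structures, fam$msa)
    rho <- cor(pairs$rmsd, pairs$identity, method = "spearman")
    expect_lt(rho, -0.5)
  }
})

test_that("synthetic search tables carry labels consistent with their thresholds", {
  st <- make_search_table(100, "iteration1", seed = 7)
  cov <- st$hits$aligned_length / st$hits$query_length
  expect_identical(st$truth$pass_label,
                   st$hits$rmsd < 2.0 & cov >= 0.80)
  # boundary probes present: exact-threshold coverage passes, exact rmsd fails
  expect_true(any(cov == 0.80 & st$truth$pass_label))
  expect_true(any(st$hits$rmsd == 2.0 & !st$truth$pass_label))
  expect_true(all(st$hits$kingdom %in%
                    c("bacteria", "fungi", "metazoa", "plantae", "protozoa")))

  empty <- make_search_table(0, "iteration1", seed = 7)
  expect_identical(nrow(empty$hits), 0L)
  expect_length(empty$truth$pass_label, 0)
  expect_error(make_search_table(10, "iteration9", seed = 1))
  expect_identical(make_search_table(50, "iteration2", 3)$hits,
                   make_search_table(50, "iteration2", 3)$hits)
})

test_that("architecture fixtures cover all novelty categories", {
  fx <- make_architecture_fixtures(seed = 2)
  expect_setequal(unique(fx$expected), c("1", "2", "3", "known"))
  expect_setequal(names(fx$expected), names(fx$architectures))
})
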