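test_that("architecture signatures follow sequence order, not input order", {
  a <- domain_architecture("p", c("trefoil"), 1, 150)
  expect_identical(architecture_signature(a), "trefoil")
  b <- domain_architecture("p", c("chitinase", "trefoil"),
                           start = c(160, 1), end = c(500, 150))
  expect_identical(architecture_signature(b), c("trefoil", "chitinase"))
  expect_error(domain_architecture("p", c("a", "b"), c(1, 50), c(100, 120)),
               "overlap")
  expect_error(domain_architecture("p", "a", 10, 5), "start")
  expect_error(domain_architecture("p", "", 1, 5), "non-empty")
})

test_that("category classification follows the three novelty patterns", {
  fx <- make_architecture_fixtures(seed = 1)
  # extra domain unknown to the catalog -> 1
  expect_identical(
    classify_category(fx$architectures$cat1_like, "trefoil", fx$catalog)$category,
    "1")
  # extra domain known, but its catalog protein lacks the trefoil even at
  # full length -> 2
  expect_identical(
    classify_category(fx$architectures$cat2_like, "trefoil", fx$catalog)$category,
    "2")
  # extra domain co-occurs with a trefoil in a catalog entry -> 3
  expect_identical(
    classify_category(fx$architectures$cat3_like, "trefoil", fx$catalog)$category,
    "3")
  # whole signature already catalogued, or no extra domain -> known
  expect_identical(
    classify_category(fx$architectures$known_solo, "trefoil", fx$catalog)$category,
    "known")
  expect_identical(
    classify_category(fx$architectures$known_pair, "trefoil", fx$catalog)$category,
    "known")
  # several extras: the most novel wins, per-domain verdicts reported
  mixed <- classify_category(fx$architectures$mixed_12, "trefoil", fx$catalog)
  expect_identical(mixed$category, "1")
  expect_setequal(mixed$per_domain$category, c("1", "2"))

  no_tref <- domain_architecture("x", "chitinase", 1, 300)
  expect_error(classify_category(no_tref, "trefoil", fx$catalog),
               "precondition")
})

test_that("full-length trefoil presence promotes category 2 to 3", {
  catalog <- architecture_catalog(list(
    e1 = list(architecture = domain_architecture("e1", "kinase", 1, 250),
              full_length_architecture = domain_architecture(
                "e1fl", c("kinase", "trefoil"), c(1, 260), c(250, 410)))))
  arch <- domain_architecture("p", c("trefoil", "kinase"),
                              c(1, 160), c(150, 410))
  expect_identical(classify_category(arch, "trefoil", catalog)$category, "3")
})

test_that("novel-architecture scan matches the fixture oracle exactly", {
  fx <- make_architecture_fixtures(seed = 6)
  novel <- find_novel_architectures(fx$architectures, fx$catalog)
  expected <- fx$expected[fx$expected != "known"]
  expect_setequal(novel$protein_id, names(expected))
  expect_identical(
    stats::setNames(novel$category, novel$protein_id)[names(expected)],
    expected)
  # deterministic order: by signature then id
  expect_identical(novel, novel[order(novel$signature, novel$protein_id), ])

  # all architectures already catalogued -> nothing novel
  all_known <- list(domain_architecture("k", c("trefoil", "agglutinin",
                                               "lectin_x"),
                                        c(1, 200, 400), c(150, 390, 550)))
  expect_identical(nrow(find_novel_architectures(all_known, fx$catalog)), 0L)

  # empty catalog -> every multi-domain trefoil protein is category 1
  novel0 <- find_novel_architectures(fx$architectures, architecture_catalog())
  multi <- names(Filter(function(a) length(architecture_signature(a)) > 1,
                        fx$architectures))
  expect_true(all(novel0$category[novel0$protein_id %in% multi] == "1"))
})

test_that("growing the catalog never makes a protein more novel", {
  rank <- c("1" = 1, "2" = 2, "3" = 3, known = 4)
  arch <- domain_architecture("p", c("trefoil", "doma", "domb"),
                              c(1, 160, 330), c(150, 320, 480))
  entries <- list(
    list(architecture = domain_architecture("c1", "doma", 1, 150)),
    list(architecture = domain_architecture("c2", c("doma", "trefoil"),
                                            c(1, 160), c(150, 310))),
    list(architecture = domain_architecture("c3", "domb", 1, 150)),
    list(architecture = domain_architecture("c4", c("trefoil", "domb"),
                                            c(1, 160), c(150, 310))),
    list(architecture = domain_architecture("c5", c("trefoil", "doma", "domb"),
                                            c(1, 160, 330), c(150, 320, 480))))
  prev <- rank[[classify_category(arch, "trefoil",
                                  architecture_catalog())$category]]
  for (m in seq_along(entries)) {
    cat_m <- architecture_catalog(stats::setNames(entries[seq_len(m)],
                                                  paste0("c", seq_len(m))))
    cur <- rank[[classify_category(arch, "trefoil", cat_m)$category]]
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_identical(prev, rank[["known"]])
})

test_that("architecture tables round-trip through TSV", {
  fx <- make_architecture_fixtures(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_architecture_table(fx$architectures, path)
  back <- read_architecture_table(path)
  expect_setequal(names(back), names(fx$architectures))
  for (id in names(back)) {
    expect_identical(architecture_signature(back[[id]]),
                     architecture_signature(fx$architectures[[id]]))
  }
  # catalog variant with the full_length flag
  cat_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_name\tstart\tend\tfull_length",
               "e1\tkinase\t1\t250\t0",
               "e1\tkinase\t1\t250\t1",
               "e1\ttrefoil\t260\t410\t1"), cat_path)
  cat2 <- read_architecture_table(cat_path)
  expect_s3_class(cat2, "architecture_catalog")
  expect_identical(
    architecture_signature(cat2$entries$e1$full_length_architecture),
    c("kinase", "trefoil"))
})
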