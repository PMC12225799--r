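test_that("structure write/read round-trips at PDB precision", {
  t1 <- make_template_structure(30, 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(t1, path)
  back <- read_structure(path)
  expect_identical(back$resno, t1$resno)
  expect_identical(back$aa, t1$aa)
  expect_equal(back$xyz, t1$xyz, tolerance = 5e-4, ignore_attr = TRUE)
})

test_that("the reader keeps Calpha atoms only and honors altLoc/HETATM rules", {
  lines <- c(
    "HEADER    TOY",
    "ATOM      1  N   ALA A   1      11.000  1.000  1.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000  2.000  3.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      12.000  1.000  1.000  1.00  0.00           C",
    "ATOM      4  CA AGLY A   2       4.000  5.000  6.000  0.50  0.00           C",
    "ATOM      5  CA BGLY A   2      40.000 50.000 60.000  0.50  0.00           C",
    "HETATM    6  CA  HOH A  90      99.000 99.000 99.000  1.00  0.00           C",
    "ATOM      7  CA  TRP A   3       7.000  8.000  9.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  expect_identical(length(s), 3L)          # CA only, altLoc A kept, B dropped
  expect_identical(s$resno, c(1L, 2L, 3L))
  expect_identical(s$aa, c("A", "G", "W"))
  expect_equal(s$xyz[1, ], c(x = 1, y = 2, z = 3))
})

test_that("reader errors carry locators and the empty case is explicit", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    X", "REMARK none", "END"), path)
  expect_error(read_structure(path), "no ATOM records")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000  2.000  3.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       xx.x0  2.000  3.000  1.00  0.00"), path)
  expect_error(read_structure(path), "line 2.*coordinate")
})

test_that("reader agrees with bio3d on a written structure", {
  skip_if_not_installed("bio3d")
  t1 <- make_template_structure(45, 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(t1, path)
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- ref$atom[ref$atom$elety == "CA", ]
  expect_identical(nrow(ca), 45L)
  expect_equal(unname(as.matrix(ca[, c("x", "y", "z")])),
               unname(round(t1$xyz, 3)))
  expect_identical(as.integer(ca$resno), t1$resno)
})

test_that("foldseek rows parse with derived coverage and kingdom", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t151\t140\t1.50\tE. coli\tBacteria;Proteobacteria",
               "P2\t151\t40\t2.50\tmoss\tEukaryota;Viridiplantae",
               "P3\t151\t40\t2.50\tmystery\tsomething;odd"), path)
  hits <- parse_foldseek_table(path)
  expect_identical(nrow(hits), 3L)
  expect_equal(hits$coverage[1], 140 / 151)
  expect_identical(hits$kingdom, c("bacteria", "plantae", "unknown"))
  expect_false(any(hits$coverage_flag))

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_identical(nrow(parse_foldseek_table(empty)), 0L)
})

test_that("foldseek parser rejects bad rows with their index", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t151\t140\t1.50\tx\ty",
               "P2\t151\tabc\t1.50\tx\ty"), path)
  expect_error(parse_foldseek_table(path), "row 2.*alnlen")
  writeLines("P1\t151\t140\t1.50\tx", path)
  expect_error(parse_foldseek_table(path), "dialect.*6")
})

test_that("foldseek table writing round-trips through the parser", {
  st <- make_search_table(25, "iteration2", seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_foldseek_table(st$hits, path)
  back <- parse_foldseek_table(path, query_id = "synthetic_query")
  expect_equal(back[, c("target_id", "query_length", "aligned_length", "rmsd",
                        "kingdom", "coverage")],
               st$hits[, c("target_id", "query_length", "aligned_length",
                           "rmsd", "kingdom", "coverage")])
})

test_that("dali summary parsing skips headers exactly and maps fields 3/4", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# Job: 5bow search",
               "Job: something",
               "Query: 5bow-A",
               "",
               "  1i1b-A  30.5  1.9  130  153  35",
               "  9xyz-A  10.1  2.8  90   160  12"), path)
  hits <- parse_dali_table(path, query_length = 151)
  expect_identical(nrow(hits), 2L)
  expect_equal(hits$rmsd, c(1.9, 2.8))
  expect_equal(hits$aligned_length, c(130, 90))
  expect_equal(hits$coverage[1], 130 / 151)
  expect_equal(hits$identity, c(0.35, 0.12))

  writeLines(c("# Job: x", "Query: y", ""), path)
  expect_identical(nrow(parse_dali_table(path, 151)), 0L)
})

test_that("fasta alignments round-trip and contract violations are loud", {
  msa <- msa_from_strings(c(s1 = "ACDEFGHIKL", s2 = "ACDE-GHIKL"))
  expect_identical(dim(msa), c(2L, 10L))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_msa(msa, path)
  expect_identical(read_fasta_msa(path), msa)

  expect_error(msa_from_strings(c(a = "ACGT", b = "ACG")), "ragged")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), path)
  expect_error(read_fasta_msa(path), "ragged")
  writeLines(c(">a", "ACDEF", ">a", "ACDEF"), path)
  expect_error(read_fasta_msa(path), "duplicate")
})
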