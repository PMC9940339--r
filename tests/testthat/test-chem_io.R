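# Molecule table I/O, standardization and the synthetic fixture library.

test_that("duplicate structures collapse to their mean activity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("smiles\tpX", "CCO\t6.0", "OCC\t7.0", "c1ccccc1\t5.0"), path)
  tbl <- read_smiles_table(path, activity_col = "pX")
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$pX[tbl$smiles == "CCO"], 6.5)
})

test_that("unusable rows are skipped and degenerate inputs error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("smiles", "CCO", "not_a_smiles", "CCN", "CCC"), path)
  expect_message(tbl <- read_smiles_table(path), "skipped 1")
  expect_equal(nrow(tbl), 3)

  writeLines("smiles", path)
  expect_error(read_smiles_table(path), "no molecule rows")
  writeLines(c("smiles", "CCO"), path)
  expect_error(read_smiles_table(path, smiles_col = "structure"),
               "not present")
})

test_that("read/write round-trip preserves canonical structures", {
  tbl <- fix_lib(20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_smiles_table(tbl, path)
  back <- read_smiles_table(path, activity_col = "pX")
  expect_setequal(back$smiles, tbl$smiles)
})

test_that("standardization strips salts, neutralizes and rejects metals", {
  std <- standardize_molecules(c("CC(=O)[O-].[Na+]", "CCO", "[Pt](Cl)Cl",
                                 "CC[NH3+].[Cl-]"))
  expect_equal(std$smiles[1], "CC(=O)O")
  expect_equal(std$smiles[2], "CCO")
  expect_false(std$ok[3])
  expect_match(std$reason[3], "metal")
  expect_equal(std$smiles[4], "CCN")
})

test_that("standardization is idempotent and flags permanent charges", {
  suppressMessages({
    s1 <- standardize_molecules(c("CC(=O)[O-].[Na+]", "C[N+](C)(C)C"))
    s2 <- standardize_molecules(s1$smiles)
  })
  expect_equal(s2$smiles, s1$smiles)
  expect_true(s1$charged[2])   # quaternary N cannot be neutralized
})

test_that("fixture library is deterministic and seed-sensitive", {
  a <- generate_fixture_library(seed = 1, n = 50)
  b <- generate_fixture_library(seed = 1, n = 50)
  c <- generate_fixture_library(seed = 2, n = 50)
  expect_identical(a, b)
  expect_false(identical(a$smiles, c$smiles))
  expect_equal(length(unique(a$smiles)), 50)
  expect_true(all(a$pX >= 3 & a$pX <= 12))
})

test_that("fixture molecules are standardization fixed points", {
  lib <- fix_lib(30)
  std <- standardize_molecules(lib$smiles)
  expect_true(all(std$ok))
  expect_equal(std$smiles, lib$smiles)
})

test_that("fixture space is bounded with an informative error", {
  expect_error(generate_fixture_library(seed = 1, n = 10^6), "maximum")
})

test_that("every fixture molecule yields at least one BRICS leaf", {
  frs <- fix_frags(30)
  expect_true(all(vapply(frs, function(f) length(f) >= 1, TRUE)))
})
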