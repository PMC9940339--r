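# Population coefficients and Solow-Polasky diversity.

test_that("Tanimoto distance follows the bit-set formula", {
  expect_equal(tanimoto_distance(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto_distance(c(5L, 9L), c(5L, 9L)), 0)
  expect_equal(tanimoto_distance(1:3, 4:6), 1)
  expect_equal(tanimoto_distance(integer(0), integer(0)), 0)
  # symmetry
  expect_equal(tanimoto_distance(c(1L, 7L), c(7L, 8L, 9L)),
               tanimoto_distance(c(7L, 8L, 9L), c(1L, 7L)))
})

test_that("Solow-Polasky matches closed forms", {
  expect_equal(solow_polasky_diversity(list(c(1L, 2L))), 1)
  # two molecules at distance 1: 1 / (1 + e^-0.5)
  expect_equal(solow_polasky_diversity(list(c(1L, 2L), c(3L, 4L))),
               1 / (1 + exp(-0.5)), tolerance = 1e-12)
  # m equidistant molecules: equicorrelated closed form
  for (m in c(3, 7, 15)) {
    fps <- lapply(seq_len(m), function(i) 10L * i + 0:1)
    a <- exp(-0.5)
    # F = (1-a) I + a J; e' F^-1 e = m / (1 - a + m a)
    expect_equal(solow_polasky_diversity(fps),
                 1 / (1 - a + m * a), tolerance = 1e-10)
  }
})

test_that("linear solve agrees with explicit inversion", {
  set.seed(11)
  for (rep in 1:5) {
    m <- sample(5:50, 1)
    fps <- lapply(seq_len(m), function(i)
      sort(sample(0:255, sample(8:30, 1))))
    key <- vapply(fps, paste, "", collapse = ",")
    fps <- fps[!duplicated(key)]
    got <- solow_polasky_diversity(fps)
    F <- exp(-0.5 * tanimoto_distance_matrix(fps))
    e <- rep(1, length(fps))
    want <- as.numeric(t(e) %*% solve(F) %*% e) / length(fps)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("adding an exact duplicate never increases diversity", {
  set.seed(12)
  fps <- lapply(1:8, function(i) sort(sample(0:127, 12)))
  base <- solow_polasky_diversity(fps)
  withdup <- solow_polasky_diversity(c(fps, fps[3]))
  expect_lte(withdup, base + 1e-12)
})

test_that("scaffold containment handles aromatic and kekulized forms", {
  expect_true(contains_scaffold("c1ccccc1", "c1ccccc1"))        # self
  expect_true(contains_scaffold("Cc1ccccc1", "c1ccccc1"))       # toluene
  expect_false(contains_scaffold("Cc1ccccc1", "n1ccccc1"))      # no pyridine
  # multi-fragment scaffolds need every fragment
  expect_true(contains_scaffold("CCOc1ccccc1", "CC.c1ccccc1"))
  expect_false(contains_scaffold("CCO", "CC.c1ccccc1"))
  # the documented kekulization mismatch: an aliphatic chain grown into an
  # aromatic ring no longer matches
  expect_false(contains_scaffold("Cc1ccccc1", "CCC"))
  expect_false(contains_scaffold(NA_character_, "C"))
})

test_that("population metrics compute the five fractions", {
  gen <- data.frame(
    scaffold = c("CC", "CC", "CC", "CC"),
    smiles = c("CCO", "CCO", "CCN", "xxx"),
    stringsAsFactors = FALSE)
  rep <- population_metrics(gen, reference = "CCO",
                            desired = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep$validity, 3 / 4)
  expect_equal(rep$accuracy, 3 / 4)          # all valid contain "CC"
  expect_equal(rep$desirability, 2 / 4)
  expect_equal(rep$uniqueness, 2 / 4)        # CCO, CCN distinct
  expect_equal(rep$novelty, 1 / 4)           # CCN only
  expect_lte(rep$n_novel, rep$n_unique)
  expect_true(all(unlist(rep[c("validity", "accuracy", "uniqueness",
                               "novelty")]) <= 1))
})

test_that("a population of one repeated structure has uniqueness 1/N", {
  gen <- data.frame(scaffold = "C", smiles = rep("CCO", 5))
  rep <- population_metrics(gen)
  expect_equal(rep$uniqueness, 1 / 5)
  expect_equal(rep$validity, 1)
  expect_equal(rep$diversity, 1)             # single distinct structure
})
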