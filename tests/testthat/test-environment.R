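# Descriptors, affinity regressor and population scoring.

test_that("descriptor vectors have the documented layout and counts", {
  X <- compute_descriptors(c("C", "c1ccccc1", "CCO"))
  expect_equal(ncol(X), 2067)
  expect_true(all(X[, 1:2048] %in% c(0, 1)))
  # methane: 1 heavy atom, no rings, no rotatable bonds
  expect_equal(unname(X[1, "HeavyAtoms"]), 1)
  expect_equal(unname(X[1, "TotalRings"]), 0)
  expect_equal(unname(X[1, "RotBonds"]), 0)
  # benzene: one aromatic ring, no heteroatoms
  expect_equal(unname(X[2, "AromaticRings"]), 1)
  expect_equal(unname(X[2, "Heteroatoms"]), 0)
  expect_equal(unname(X[2, "ValenceElectrons"]), 30)
  # determinism
  expect_identical(X, compute_descriptors(c("C", "c1ccccc1", "CCO")))
  # unparsable rows are NA
  expect_true(all(is.na(compute_descriptors("nope")[1, ])))
})

test_that("the affinity model recovers the planted signal", {
  lib <- fix_lib(120)
  half <- seq_len(60)
  am <- suppressWarnings(train_affinity_model(lib[half, ], ntree = 150,
                                              seed = 3))
  pred <- predict(am, lib$smiles[-half])
  truth <- lib$pX[-half]
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  expect_gt(1 - ss_res / ss_tot, 0)     # beats the mean predictor
  expect_true(all(is.finite(predict(am, lib$smiles[half]))))
  # reproducibility under the seed
  am2 <- train_affinity_model(lib[half, ], ntree = 150, seed = 3)
  expect_equal(predict(am2, lib$smiles[61:70]), pred[1:10])
})

test_that("degenerate activity tables are rejected", {
  lib <- fix_lib(40)
  expect_error(train_affinity_model(lib[1:10, ]), "at least 25")
  const <- lib; const$pX <- 5
  expect_error(train_affinity_model(const), "constant")
})

test_that("the desired flag follows the pX 6.5 threshold inclusively", {
  scorer <- function(smiles) c(7.0, 6.5, 6.49)[seq_along(smiles)]
  sc <- score_population(c("CCO", "CCN", "CCC"), scorer)
  expect_equal(sc$desired, c(TRUE, TRUE, FALSE))
  expect_equal(sc$affinity, c(7.0, 6.5, 6.49))
})

test_that("scoring is total over parse failures and a pure function", {
  am <- fix_affinity_model()
  smi <- c(fix_lib(10)$smiles[1:4], "not_a_smiles")
  sc <- score_population(smi, am)
  expect_false(sc$valid[5])
  expect_false(sc$desired[5])
  expect_equal(sc$qed[5], 0)
  expect_equal(sc$sa[5], 10)
  expect_true(all(sc$qed[1:4] >= 0 & sc$qed[1:4] <= 1))
  expect_true(all(sc$sa[1:4] >= 1 & sc$sa[1:4] <= 10))
  perm <- c(3, 1, 5, 2, 4)
  sc2 <- score_population(smi[perm], am)
  expect_equal(sc2$affinity, sc$affinity[perm])
  expect_equal(sc2$qed, sc$qed[perm])
})

test_that("a QED cutoff tightens the desired flag when configured", {
  scorer <- function(smiles) rep(9, length(smiles))
  smi <- fix_lib(10)$smiles[1:5]
  plain <- score_population(smi, scorer)
  strict <- score_population(smi, scorer, qed_cutoff = 2)  # unreachable
  expect_true(all(plain$desired))
  expect_false(any(strict$desired))
})
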