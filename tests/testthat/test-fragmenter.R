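# BRICS fragmentation, pair enumeration and scaffold splitting.

test_that("molecules without cleavable bonds are their own fragment", {
  fr <- brics_leaf_fragments(c("c1ccccc1", "CCC"))
  expect_equal(fr[[1]], "c1ccccc1")
  expect_equal(fr[[2]], "CCC")
})

test_that("aspirin decomposes into its BRICS leaf set", {
  # frozen from a hand application of the BRICS cleavage rules: the ester
  # splits at both acyl/ether environments, the acid at the acyl bond
  fr <- brics_leaf_fragments("CC(=O)Oc1ccccc1C(=O)O")[[1]]
  expect_setequal(fr, c("c1ccccc1", "CC=O", "O=CO", "O"))
  # largest-first by heavy atoms
  expect_equal(fr[1], "c1ccccc1")
})

test_that("at most four fragments are kept, largest first", {
  frs <- fix_frags(40)
  lens <- lengths(frs)
  expect_true(all(lens >= 1 & lens <= 4))
  heavy <- function(s) {
    n <- nchar(gsub("[^A-Za-z]", "", gsub("Cl|Br", "X", s)))
    n
  }
  for (fr in frs[lens > 1]) {
    h <- vapply(fr, heavy, 0)
    expect_true(all(diff(h) <= 0))
  }
})

test_that("pair enumeration yields 2^n - 1 subsets", {
  # oracle: explicit subset enumeration
  for (n in 1:4) {
    frags <- paste0("F", seq_len(n))
    p <- enumerate_pairs(frags, "MOL", seed = 3)
    expect_equal(nrow(p), 2^n - 1)
    expect_equal(sort(p$subset_size),
                 sort(lengths(unlist(lapply(seq_len(n), function(k)
                   utils::combn(n, k, simplify = FALSE)), recursive = FALSE))))
    # each scaffold is a distinct subset regardless of internal order
    key <- vapply(strsplit(p$scaffold, ".", fixed = TRUE),
                  function(x) paste(sort(x), collapse = "."), "")
    expect_equal(length(unique(key)), 2^n - 1)
  }
})

test_that("pair sets are seed-invariant, fragment order is not", {
  frags <- c("CCO", "c1ccccc1", "CCN")
  p1 <- enumerate_pairs(frags, "M", seed = 1)
  p2 <- enumerate_pairs(frags, "M", seed = 2)
  key <- function(p) sort(vapply(strsplit(p$scaffold, ".", fixed = TRUE),
                                 function(x) paste(sort(x), collapse = "."),
                                 ""))
  expect_equal(key(p1), key(p2))
  orders_differ <- vapply(1:50, function(s)
    !identical(enumerate_pairs(frags, "M", seed = s)$scaffold, p1$scaffold),
    TRUE)
  expect_true(any(orders_differ))
})

test_that("every emitted fragment is a substructure of its molecule", {
  pairs <- fix_pairs(25)
  sub <- pairs[sample.int(nrow(pairs), min(30, nrow(pairs))), ]
  expect_true(all(contains_scaffold(sub$molecule, sub$scaffold)))
})

test_that("scaffold split partitions distinct scaffolds 8:1:1", {
  pairs <- fix_pairs(40)
  sp <- scaffold_split(pairs, seed = 4)
  keys <- lapply(sp, function(p)
    unique(vapply(strsplit(p$scaffold, ".", fixed = TRUE),
                  function(x) paste(sort(x), collapse = "."), "")))
  expect_length(intersect(keys$train, keys$valid), 0)
  expect_length(intersect(keys$train, keys$test), 0)
  expect_length(intersect(keys$valid, keys$test), 0)
  n <- length(unique(c(keys$train, keys$valid, keys$test)))
  expect_equal(length(keys$valid), ceiling(n / 10))
  expect_equal(length(keys$test), ceiling(n / 10))
  expect_equal(nrow(sp$train) + nrow(sp$valid) + nrow(sp$test), nrow(pairs))
  # determinism
  sp2 <- scaffold_split(pairs, seed = 4)
  expect_identical(sp, sp2)
})

test_that("splitting fewer than three scaffolds errors", {
  pairs <- data.frame(scaffold = c("CC", "CC"), molecule = c("CCO", "CCN"),
                      subset_size = 1)
  expect_error(scaffold_split(pairs), "at least 3")
})
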