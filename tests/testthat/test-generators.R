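# Generator training and scaffold-conditioned sampling.

test_that("training loss decreases over the first epochs for all kinds", {
  pairs <- fix_pairs(15, max_subset_size = 1)
  pairs <- pairs[seq_len(min(12, nrow(pairs))), ]
  sv <- smiles_vocab(c(pairs$scaffold, pairs$molecule))
  gv <- graph_vocab()
  for (kind in c("graph-transformer", "seq-transformer", "lstm-base",
                 "lstm-attn")) {
    cfg <- if (kind == "graph-transformer") tiny_graph_config()
           else tiny_seq_config(kind)
    vocab <- if (kind == "graph-transformer") gv else sv
    m <- new_generator(kind, vocab, cfg, seed = 3)
    m <- suppressMessages(train_generator(
      m, pairs, pairs, train_config(lr = 1e-3, batch_size = 12, epochs = 5,
                                    seed = 1), quiet = TRUE))
    expect_lt(tail(m$trace$train_nll, 1), m$trace$train_nll[1])
    expect_true(all(is.finite(m$trace$valid_nll)))
    expect_gt(m$trace$train_nll[1], 0)
  }
})

test_that("early stopping halts at best epoch + patience", {
  pairs <- fix_pairs(15, max_subset_size = 1)[1:8, ]
  sv <- smiles_vocab(c(pairs$scaffold, pairs$molecule))
  m <- new_generator("lstm-base", sv, tiny_seq_config("lstm-base"), seed = 2)
  m <- suppressMessages(train_generator(
    m, pairs, pairs, train_config(lr = 1e-12, batch_size = 8, epochs = 50,
                                  patience = 3, seed = 1), quiet = TRUE))
  # a vanishing learning rate freezes the validation loss within the
  # improvement threshold, so epoch 1 stays the best
  expect_equal(m$best_epoch, 1)
  expect_equal(nrow(m$trace), 1 + 3)
})

test_that("sampling is deterministic under a fixed seed", {
  pairs <- fix_pairs(15, max_subset_size = 1)
  sv <- smiles_vocab(c(pairs$scaffold, pairs$molecule))
  m <- new_generator("seq-transformer", sv, tiny_seq_config("seq-transformer"),
                     seed = 5)
  s1 <- sample_molecules(m, pairs$scaffold[1:3], k = 4, seed = 9)
  s2 <- sample_molecules(m, pairs$scaffold[1:3], k = 4, seed = 9)
  s3 <- sample_molecules(m, pairs$scaffold[1:3], k = 4, seed = 10)
  expect_identical(s1$smiles, s2$smiles)
  expect_false(identical(s1$smiles, s3$smiles))
  expect_equal(nrow(s1), 12)
  expect_equal(s1$scaffold, rep(pairs$scaffold[1:3], each = 4))

  gm <- new_generator("graph-transformer", graph_vocab(),
                      tiny_graph_config(), seed = 5)
  g1 <- sample_molecules(gm, pairs$scaffold[1:2], k = 3, seed = 9)
  g2 <- sample_molecules(gm, pairs$scaffold[1:2], k = 3, seed = 9)
  expect_identical(g1$smiles, g2$smiles)
})

test_that("untrained graph sampling is 100% parsable (valence masking)", {
  gm <- new_generator("graph-transformer", graph_vocab(),
                      tiny_graph_config(), seed = 8)
  s <- sample_molecules(gm, c("c1ccco1", "Nc1nc(N)nc(N)n1", "CCO.CC=O"),
                        k = 15, seed = 4)
  expect_equal(sum(is.na(s$smiles)), 0)
  expect_true(all(is_valid_smiles(s$smiles)))
})

test_that("training rejects degenerate inputs", {
  sv <- smiles_vocab("CC")
  m <- new_generator("lstm-base", sv, tiny_seq_config("lstm-base"), seed = 1)
  empty <- data.frame(scaffold = character(0), molecule = character(0))
  expect_error(suppressWarnings(suppressMessages(
    train_generator(m, empty, empty, train_config(epochs = 1)))))
})
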