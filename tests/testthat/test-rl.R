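# Policy-gradient reinforcement learning.

test_that("the exploring rate is validated", {
  expect_error(rl_config(epsilon = -0.1), "\\[0, 1\\]")
  expect_error(rl_config(epsilon = 1.2), "\\[0, 1\\]")
  expect_silent(rl_config(epsilon = 0))
  expect_silent(rl_config(epsilon = 1))
})

test_that("REINFORCE drives a two-action bandit to the rewarded action", {
  # vocabulary of two tokens; reward 1 for token 1, 0 for token 2
  set.seed(3)
  W <- ad_param(matrix(0, 1, 2))
  opt <- adam_init(list(W = W))
  x <- matrix(1, 1, 1)
  for (step in 1:200) {
    p <- exp(W$val) / sum(exp(W$val))
    a <- sample(1:2, 1, prob = p)
    r <- as.numeric(a == 1)
    loss <- ad_pg_loss(ad_matmul(x, W), a, r)
    ad_backward(loss)
    opt <- adam_step(opt, list(W = W), lr = 0.05)
  }
  p_final <- exp(W$val) / sum(exp(W$val))
  expect_gt(p_final[1], 0.95)
})

test_that("the frozen exploration net is bit-identical after training", {
  pairs <- fix_pairs(25, max_subset_size = 1)
  gv <- graph_vocab()
  agent <- new_generator("graph-transformer", gv, tiny_graph_config(),
                         seed = 4)
  frozen <- new_generator("graph-transformer", gv, tiny_graph_config(),
                          seed = 5)
  ck <- generator_checksum(frozen)
  scorer <- function(smiles) rep(7, length(smiles))
  res <- suppressMessages(rl_train(
    agent, frozen, unique(pairs$scaffold)[1:6], scorer,
    rl_config(epsilon = 0.5, epochs = 2, batch = 8, lr = 1e-3, seed = 2)))
  expect_identical(generator_checksum(frozen), ck)
  expect_equal(nrow(res$metrics), 2)
  expect_true(all(res$metrics$mean_reward > 0 &
                  res$metrics$mean_reward <= 1))
})

test_that("epsilon 0 never consults the exploration net", {
  pairs <- fix_pairs(25, max_subset_size = 1)
  gv <- graph_vocab()
  agent <- new_generator("graph-transformer", gv, tiny_graph_config(),
                         seed = 4)
  # a poisoned stand-in: any call would error out
  trap <- structure(list(kind = "graph-transformer"), class = "not_a_model")
  scorer <- function(smiles) rep(7, length(smiles))
  expect_silent(suppressMessages(rl_train(
    agent, NULL, unique(pairs$scaffold)[1:4], scorer,
    rl_config(epsilon = 0, epochs = 1, batch = 6, lr = 1e-3, seed = 2))))
})

test_that("policy-gradient updates move probability toward reward", {
  # agent rewarded for emitting molecules containing nitrogen: after a few
  # updates the fraction of N-containing emissions should not collapse
  pairs <- fix_pairs(25, max_subset_size = 1)
  gv <- graph_vocab()
  agent <- new_generator("graph-transformer", gv, tiny_graph_config(),
                         seed = 6)
  scorer <- function(smiles) 5 + 3 * grepl("N", smiles, fixed = TRUE)
  scaf <- unique(pairs$scaffold)[1:6]
  before <- sample_molecules(agent, scaf, k = 4, seed = 31)
  frac_before <- mean(grepl("N", before$smiles, fixed = TRUE))
  res <- suppressMessages(rl_train(
    agent, NULL, scaf, scorer,
    rl_config(epsilon = 0, epochs = 8, batch = 16, lr = 2e-3, seed = 3)))
  after <- sample_molecules(res$agent, scaf, k = 4, seed = 31)
  frac_after <- mean(grepl("N", after$smiles, fixed = TRUE))
  expect_gte(frac_after, frac_before - 0.25)
  expect_true(all(diff(range(res$metrics$epoch)) == 7))
})
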