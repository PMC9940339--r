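# Pareto dominance, non-dominated sorting and rank rewards.
# (the brute-force frontier oracle lives in helper-oracles.R)

test_that("dominance follows the weak/strict definition", {
  expect_true(dominates(c(0.8, 0.9), c(0.7, 0.9)))
  expect_false(dominates(c(0.8, 0.9), c(0.8, 0.9)))          # x vs x
  expect_false(dominates(c(0.8, 0.5), c(0.5, 0.8)))          # incomparable
  expect_false(dominates(c(0.5, 0.8), c(0.8, 0.5)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("degenerate populations sort as expected", {
  # mutually non-dominated: one frontier
  s <- matrix(c(1, 0, 0.5, 0, 1, 0.4), 3, 2)
  expect_length(non_dominated_sort(s), 1)
  # strictly ordered chain: singleton frontiers
  chain <- matrix(c(3, 2, 1, 3, 2, 1), 3, 2)
  fr <- non_dominated_sort(chain)
  expect_equal(fr, list(1L, 2L, 3L))
})

test_that("non-dominated sort matches the recursive oracle", {
  set.seed(42)
  for (rep in 1:200) {
    N <- sample(2:60, 1)
    n <- sample(2:4, 1)
    s <- matrix(round(runif(N * n), 2), N, n)  # rounding forces ties
    fronts <- non_dominated_sort(s)
    got <- integer(N)
    for (f in seq_along(fronts)) got[fronts[[f]]] <- f
    expect_equal(got, .oracle_frontiers(s))
    expect_setequal(unlist(fronts), seq_len(N))
  }
})

test_that("within-frontier ordering puts crowded molecules first", {
  fps <- list(c(1L, 2L, 3L), c(1L, 2L, 3L), c(90L, 91L))
  ord <- order_within_frontier(1:3, fps, smiles = c("A", "B", "C"))
  expect_equal(ord[3], 3)               # the distinct one is last
  expect_equal(sort(ord[1:2]), 1:2)     # duplicates occupy the first slots
  # permutation invariance
  perm <- c(3, 1, 2)
  ord2 <- order_within_frontier(perm, fps, smiles = c("A", "B", "C"))
  expect_equal(sort(ord2), sort(perm))
  expect_equal(ord2[3], 3)
  expect_equal(order_within_frontier(5L, fps), 5L)   # singleton unchanged
})

test_that("rank rewards reproduce the worked examples", {
  mk <- function(k, desired, n_des, n_und) {
    structure(data.frame(frontier = 1L, k = k, desired = desired),
              n_desired = n_des, n_undesired = n_und)
  }
  r <- assign_rewards(mk(1:5, c(FALSE, FALSE, TRUE, TRUE, TRUE), 3, 2))
  expect_equal(r, c(0.25, 0.5, 2 / 3, 5 / 6, 1.0))
  r2 <- assign_rewards(mk(1:4, rep(TRUE, 4), 4, 0))
  expect_equal(r2, c(0.625, 0.75, 0.875, 1.0))
})

test_that("rewards partition (0, 1] by desirability over random populations", {
  set.seed(7)
  for (rep in 1:60) {
    N <- sample(3:60, 1)
    scores <- matrix(runif(2 * N), N, 2)
    desired <- runif(N) < 0.5
    if (all(desired)) desired[1] <- FALSE
    if (!any(desired)) desired[1] <- TRUE
    rank <- pareto_ranking(scores, desired)
    expect_setequal(rank$k, seq_len(N))          # k is a bijection
    r <- assign_rewards(rank)
    expect_true(all(r > 0 & r <= 1))
    expect_true(all(r[rank$desired] > 0.5))
    expect_true(all(r[!rank$desired] <= 0.5))
  }
})

test_that("ranking never places a molecule above its dominator", {
  set.seed(8)
  scores <- matrix(runif(40), 20, 2)
  desired <- rep(c(TRUE, FALSE), 10)
  rank <- pareto_ranking(scores, desired)
  for (i in 1:20) for (j in 1:20) {
    if (dominates(scores[i, ], scores[j, ]))
      expect_lt(rank$frontier[i], rank$frontier[j])
  }
})

test_that("invalid molecules rank below every valid undesired molecule", {
  scores <- matrix(runif(12), 6, 2)
  desired <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  valid <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  rank <- pareto_ranking(scores, desired, valid = valid)
  expect_true(all(rank$k[!valid] < min(rank$k[valid & !desired])))
  expect_true(all(is.na(rank$frontier[!valid])))
  expect_false(any(rank$desired[!valid]))
})
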