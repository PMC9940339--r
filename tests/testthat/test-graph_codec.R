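# Five-row graph matrix codec and the valence-mask state machine.

test_that("graph vocabulary has 38 atom tokens and exactly 4 bond types", {
  v <- graph_vocab()
  expect_length(v$bond_types, 4)
  expect_equal(length(v$tokens) - 3, 38)  # *, GO, EOS + atoms
  expect_equal(v$tokens[1], "*")
  expect_equal(unname(v$index[["*"]]), 0)
})

test_that("word index W = T_atom * 4 + T_bond is injective", {
  v <- graph_vocab()
  grid <- expand.grid(a = seq_along(v$tokens) - 1L, b = 0:3)
  w <- graph_word_index(grid$a, grid$b, length(v$tokens))
  expect_equal(length(unique(w)), nrow(grid))
  expect_equal(graph_word_index(0, 0), 0)
  expect_equal(graph_word_index(1, 3), 7)
  expect_equal(graph_word_index(9, 2), 38)
  expect_error(graph_word_index(0, 4), "out of range")
})

test_that("position index P = I_atom * L_max + I_connected", {
  expect_equal(graph_position_index(0, 0, 80), 0)
  expect_equal(graph_position_index(2, 1, 80), 161)
  expect_equal(graph_position_index(1, 1, 100), 101)
  expect_error(graph_position_index(80, 0, 80), "out of range")
  # injectivity over valid pairs
  grid <- expand.grid(a = 0:19, b = 0:19)
  expect_equal(length(unique(graph_position_index(grid$a, grid$b, 20))),
               nrow(grid))
})

test_that("benzene encodes with kekulized alternating bonds", {
  v <- graph_vocab()
  m <- encode_graph("c1ccccc1", "c1ccccc1", v, 30)
  ring <- m["bond", m["bond", ] > 0]
  expect_setequal(unique(ring), c(1, 2))   # single and double only
  expect_equal(sum(ring == 2), 3)          # three double bonds
  expect_equal(decode_graph(m, v), "c1ccccc1")
})

test_that("the smallest molecule is one fragment column plus EOS", {
  v <- graph_vocab()
  m <- encode_graph("C", "C", v, 10)
  expect_equal(sum(m["atom", ] == v$index[["EOS"]]), 2)
  expect_equal(sum(m["frag", ] > 0), 1)
  expect_equal(decode_graph(m, v), "C")
})

test_that("an effectively empty matrix fails to decode", {
  v <- graph_vocab()
  m <- empty_graph_matrix(10)
  m["atom", 1] <- v$index[["EOS"]]
  expect_true(is.na(decode_graph(m, v)))
  det <- decode_graphs(list(m), v, details = TRUE)
  expect_match(det$reason, "empty")
})

test_that("encode/decode round-trips molecules over fragment subsets", {
  v <- graph_vocab()
  lib <- fix_lib(25)
  frs <- fix_frags(25)
  items <- list()
  for (i in seq_len(nrow(lib))) {
    fr <- frs[[i]]
    for (size in seq_along(fr)) {
      for (cmb in utils::combn(length(fr), size, simplify = FALSE)) {
        items[[length(items) + 1]] <-
          list(molecule = lib$smiles[i], frags = fr[cmb])
      }
    }
  }
  mats <- encode_graphs(items, v, 80)
  expect_true(all(!vapply(mats, is.null, TRUE)))
  dec <- decode_graphs(mats, v)
  want <- vapply(items, function(x) x$molecule, "")
  expect_equal(dec, want)
})

test_that("linking sections contain only single bonds", {
  v <- graph_vocab()
  lib <- fix_lib(25)
  frs <- fix_frags(25)
  multi <- which(lengths(frs) >= 2)[1:5]
  items <- lapply(multi, function(i)
    list(molecule = lib$smiles[i], frags = frs[[i]]))
  mats <- encode_graphs(items, v, 80)
  for (m in mats) {
    eos_cols <- which(m["atom", ] == v$index[["EOS"]])
    if (diff(eos_cols) > 1) {
      link <- m[, (eos_cols[1] + 1):(eos_cols[2] - 1), drop = FALSE]
      expect_true(all(link["bond", ] == 1))
      expect_true(all(link["frag", ] == 0))
    }
  }
})

test_that("valence mask tracks remaining valence per atom", {
  v <- graph_vocab()
  # methane fully saturated: C bonded to 4 neighbors
  pref <- scaffold_prefixes("C", v)[[1]]
  st <- graph_state_init(pref, v, 30)
  for (i in 1:4) {
    col <- c(v$index[["C"]], 1L, 1L, length(st$tokens) + 1L, 0L)
    st <- graph_state_step(st, col, v)
  }
  mk <- valence_mask(st, v)
  expect_false(1 %in% mk$conn)            # saturated carbon not connectable
  # fresh nitrogen: single, double, triple all allowed
  st2 <- graph_state_init(scaffold_prefixes("N", v)[[1]], v, 30)
  expect_setequal(valence_mask(st2, v)$bond, 1:3)
  # oxygen holding a double bond: no further bond to it
  st3 <- graph_state_init(scaffold_prefixes("O", v)[[1]], v, 30)
  st3 <- graph_state_step(st3, c(v$index[["C"]], 2L, 1L, 2L, 0L), v)
  mk3 <- valence_mask(st3, v)
  expect_false(1 %in% mk3$conn)           # oxygen spent
  expect_true(2 %in% mk3$conn)            # carbon still has 2 left
})

test_that("the end token is always permitted", {
  v <- graph_vocab()
  eos <- unname(v$index[["EOS"]])
  prefs <- scaffold_prefixes(c("C", "c1ccccc1", "O=CO.CC=O"), v)
  for (pref in prefs) {
    st <- graph_state_init(pref, v, 40)
    expect_true(eos %in% valence_mask(st, v)$atom)
  }
})

test_that("random-policy mask sampling always decodes", {
  v <- graph_vocab()
  prefs <- scaffold_prefixes(c("c1ccco1", "CCC.Nc1ncn[nH]1"), v)
  mats <- sample_masked_random(300, prefs, v, L = 50, seed = 21)
  dec <- decode_graphs(mats, v)
  expect_equal(sum(is.na(dec)), 0)
})
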