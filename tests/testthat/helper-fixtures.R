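# Shared fixtures, memoized so expensive objects (bridge calls, trained
# models) are built once per test run.

.fixcache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixcache[[key]])) .fixcache[[key]] <- builder()
  .fixcache[[key]]
}

fix_lib <- function(n = 60, seed = 1) {
  memo(sprintf("lib_%d_%d", n, seed),
       function() generate_fixture_library(seed = seed, n = n))
}

fix_pairs <- function(n = 60, seed = 1, max_subset_size = 2) {
  memo(sprintf("pairs_%d_%d_%s", n, seed, max_subset_size), function() {
    suppressMessages(build_pair_table(fix_lib(n, seed), seed = seed,
                                      max_subset_size = max_subset_size))
  })
}

fix_frags <- function(n = 60, seed = 1) {
  memo(sprintf("frags_%d_%d", n, seed),
       function() brics_leaf_fragments(fix_lib(n, seed)$smiles))
}

tiny_graph_config <- function(max_len = 60L) {
  generator_config("graph-transformer", d_model = 64L, heads = 4L,
                   n_layers = 2L, d_ff = 128L, max_len = max_len)
}

tiny_seq_config <- function(kind, max_len = 60L) {
  generator_config(kind, d_model = 64L, heads = 4L, n_layers = 2L,
                   d_ff = 128L, emb = 32L, hidden = 64L, rec_layers = 2L,
                   max_len = max_len)
}

# the pretrained desk-scale graph model shared by the validity and RL
# acceptance checks: 300-molecule library, 30 epochs
acceptance_graph_model <- function() {
  memo("acc_graph_model", function() {
    lib <- fix_lib(300)
    pairs <- fix_pairs(300, max_subset_size = 2)
    model <- new_generator("graph-transformer", graph_vocab(),
                           tiny_graph_config(), seed = 11)
    suppressMessages(train_generator(
      model, pairs, pairs[seq(1, nrow(pairs), by = 5), ],
      train_config(lr = 1e-3, batch_size = 64, epochs = 30, seed = 11),
      quiet = TRUE))
  })
}

# planted-signal scorer: family base activity recovered from structure by
# substructure matching against the library (fast scorer for RL tests)
fix_affinity_model <- function() {
  memo("affinity_model", function() {
    suppressMessages(train_affinity_model(fix_lib(300), ntree = 200,
                                          seed = 5))
  })
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_setequal(as.character(a), as.character(b))
}
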