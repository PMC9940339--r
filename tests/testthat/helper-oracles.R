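# Independent brute-force oracles used against the package implementations.

# frontier of each point = 1 + max frontier among its dominators, by
# direct recursion over the pairwise dominance relation (O(N^2 n))
.oracle_frontiers <- function(scores) {
  N <- nrow(scores)
  front <- rep(NA_integer_, N)
  level <- function(i) {
    if (!is.na(front[i])) return(front[i])
    doms <- which(vapply(seq_len(N), function(j)
      j != i && dominates(scores[j, ], scores[i, ]), TRUE))
    f <- if (length(doms) == 0) 1L
         else 1L + max(vapply(doms, level, 0L))
    front[i] <<- f
    f
  }
  vapply(seq_len(N), level, 0L)
}
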