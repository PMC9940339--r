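# SMILES tokenization and sequence encoding for the sequence generators.
#
# Tokens: bracket atoms (one token per [...] group), two-letter organic
# subset atoms (Cl, Br), single-letter atoms (aromatic lowercase included),
# bonds, parentheses, ring-closure digits (%nn counts as one token) and '.'.
# The vocabulary maps token -> 0-based index with three control tokens:
# blank padding "_" (index 0), "GO" and "EOS".

.smiles_two_letter <- c("Cl", "Br")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atom, bond and grammar tokens such that
#' `paste(tokens, collapse = "")` reproduces the input exactly.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens (length 0 for the empty string).
#' @export
#' @examples \dontrun{tokenize_smiles("CCl")  # "C", "Cl"}
tokenize_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  s <- as.character(smiles)
  if (!nzchar(s)) return(character(0))
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1
  legal <- c(LETTERS, letters, as.character(0:9),
             "@", "+", "-", "(", ")", "=", "#", "/", "\\", ".", ":", "*")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop(sprintf("unclosed bracket atom at offset %d", i))
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else if (ch == "%") {
      if (i + 2 > n) stop(sprintf("truncated %% ring bond at offset %d", i))
      toks <- c(toks, paste(chars[i:(i + 2)], collapse = ""))
      i <- i + 3
    } else if (i < n && paste0(ch, chars[i + 1]) %in% .smiles_two_letter) {
      toks <- c(toks, paste0(ch, chars[i + 1]))
      i <- i + 2
    } else if (ch %in% legal) {
      toks <- c(toks, ch)
      i <- i + 1
    } else {
      stop(sprintf("unknown SMILES character '%s' at offset %d", ch, i))
    }
  }
  toks
}

#' Build a SMILES vocabulary
#'
#' Collects every token occurring in a corpus on top of a frozen default
#' list covering common drug-like SMILES, and assigns dense 0-based
#' indices with control tokens `_` (blank padding, index 0), `GO` (start)
#' and `EOS` (end).
#'
#' @param corpus Character vector of SMILES (may be empty).
#' @return An object of class `smiles_vocab`: list with `tokens`
#'   (index order) and `index` (named integer map, 0-based).
#' @export
smiles_vocab <- function(corpus = character(0)) {
  default <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F", "Cl", "Br",
               "I", "B", "(", ")", "=", "#", "-", "/", "\\", ".",
               as.character(1:9), "[nH]", "[N+]", "[O-]", "[n+]", "[S+]",
               "[NH+]", "[NH2+]", "[NH3+]", "[C@H]", "[C@@H]", "[C@]",
               "[C@@]")
  seen <- unique(unlist(lapply(corpus, tokenize_smiles)))
  tokens <- c("_", "GO", "EOS", union(default, seen))
  idx <- seq_along(tokens) - 1L
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx), class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat(sprintf("<smiles_vocab: %d tokens>\n", length(x$tokens)))
  invisible(x)
}

#' Write / read a vocabulary as one token per line (line order = index)
#' @param vocab A `smiles_vocab`.
#' @param path File path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path)
  idx <- seq_along(tokens) - 1L
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx), class = "smiles_vocab")
}

#' Encode a SMILES string to a fixed-length index vector
#'
#' Adds `GO` at the start and `EOS` at the end, then pads with the blank
#' token to length `L`.
#'
#' @param smiles SMILES string.
#' @param vocab A `smiles_vocab`.
#' @param L Maximum sequence length including the two control tokens.
#' @return Integer vector of length `L` (0-based token indices).
#' @export
encode_smiles <- function(smiles, vocab, L = 100L) {
  toks <- tokenize_smiles(smiles)
  unknown <- setdiff(toks, vocab$tokens)
  if (length(unknown) > 0)
    stop("tokens not in vocabulary: ", paste(unknown, collapse = " "))
  if (length(toks) + 2 > L)
    stop(sprintf("sequence needs %d positions but L = %d",
                 length(toks) + 2, L))
  ids <- unname(vocab$index[c("GO", toks, "EOS")])
  c(ids, rep(0L, L - length(ids)))
}

#' Decode an index vector back to a SMILES string
#'
#' Inverse of [encode_smiles()]: strips padding and control tokens.
#' @param ids Integer vector of 0-based token indices.
#' @param vocab A `smiles_vocab`.
#' @return SMILES string.
#' @export
decode_smiles <- function(ids, vocab) {
  toks <- vocab$tokens[ids + 1L]
  toks <- toks[!toks %in% c("_")]
  if (length(toks) && toks[1] == "GO") toks <- toks[-1]
  eos <- which(toks == "EOS")
  if (length(eos)) toks <- toks[seq_len(eos[1] - 1L)]
  paste(toks, collapse = "")
}

#' Encode a scaffold-molecule pair
#'
#' @param scaffold Scaffold SMILES ('.'-joined fragments).
#' @param molecule Molecule SMILES.
#' @inheritParams encode_smiles
#' @return List with integer vectors `input` and `output`, both length `L`.
#' @export
encode_smiles_pair <- function(scaffold, molecule, vocab, L = 100L) {
  list(input = encode_smiles(scaffold, vocab, L),
       output = encode_smiles(molecule, vocab, L))
}

#' Encode a pair table into input/output index matrices
#'
#' Over-length pairs are dropped with a logged count.
#'
#' @param pairs Pair table (`scaffold`, `molecule`).
#' @param vocab A `smiles_vocab`.
#' @param L Maximum sequence length.
#' @return List with integer matrices `input`, `output` (rows = pairs) and
#'   the row index `kept` into `pairs`.
#' @export
encode_smiles_pairs <- function(pairs, vocab, L = 100L) {
  n <- nrow(pairs)
  inp <- matrix(0L, n, L); out <- matrix(0L, n, L)
  kept <- logical(n)
  for (i in seq_len(n)) {
    enc <- tryCatch(
      encode_smiles_pair(pairs$scaffold[i], pairs$molecule[i], vocab, L),
      error = function(e) NULL)
    if (is.null(enc)) next
    inp[i, ] <- enc$input; out[i, ] <- enc$output; kept[i] <- TRUE
  }
  if (any(!kept))
    scafgen_log("encode_smiles_pairs: dropped %d over-length/unknown pair(s)",
                sum(!kept))
  list(input = inp[kept, , drop = FALSE], output = out[kept, , drop = FALSE],
       kept = which(kept))
}
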