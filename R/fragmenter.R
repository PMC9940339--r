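# BRICS fragmentation, scaffold-molecule pair enumeration and
# scaffold-based train/validation/test splitting.
#
# A molecule is decomposed into its BRICS leaf fragments (attachment-point
# dummies stripped, open valences hydrogen-capped).  Every non-empty subset
# of the retained fragments becomes one scaffold, joined with '.', and is
# paired with the full molecule: a molecule with n fragments yields
# 2^n - 1 input-output pairs.

#' BRICS leaf fragments of molecules
#'
#' Decomposes each molecule with the BRICS bond-cleavage rules down to its
#' leaf (non-further-cleavable) fragments.  Attachment dummies are removed
#' and open valences are hydrogen-capped.  If a molecule has more than
#' `max_fragments` leaves only the largest by heavy-atom count are kept
#' (ties broken by canonical-SMILES order); fragments are listed
#' largest-first.  Molecules with no cleavable bonds yield themselves as a
#' single fragment.
#'
#' @param smiles Character vector of standardized SMILES.
#' @param max_fragments Maximum number of fragments retained per molecule.
#' @return A list (one element per molecule) of character vectors of
#'   fragment SMILES; `NULL` for unparsable molecules.
#' @export
#' @examples \dontrun{brics_leaf_fragments("CC(=O)Oc1ccccc1C(=O)O")}
brics_leaf_fragments <- function(smiles, max_fragments = 4L) {
  stopifnot(length(smiles) >= 1)
  res <- chem_call("brics", smiles = as.list(as.character(smiles)))
  lapply(res$fragments, function(fr) {
    if (is.null(fr)) return(NULL)
    smi <- vapply(fr, function(f) f$smiles, "")
    heavy <- vapply(fr, function(f) f$heavy, 0)
    if (length(smi) == 0) return(NULL)
    ord <- order(-heavy, smi)
    smi[ord][seq_len(min(length(smi), max_fragments))]
  })
}

#' Enumerate scaffold-molecule pairs
#'
#' Forms one pair per non-empty subset of a molecule's fragments: the
#' subset's fragment SMILES, joined with '.', is the scaffold (input) and
#' the full molecule SMILES is the output.  The order of fragments inside
#' each scaffold is randomized under `seed`; the set of pairs itself is
#' seed-invariant.
#'
#' @param fragments Character vector of fragment SMILES (length n, n <= 4
#'   recommended: the pair count is 2^n - 1).
#' @param molecule Full molecule SMILES.
#' @param seed Integer seed for fragment-order randomization.
#' @return data.frame with columns `scaffold`, `molecule`, `subset_size`.
#' @export
enumerate_pairs <- function(fragments, molecule, seed = 1L) {
  n <- length(fragments)
  stopifnot(n >= 1)
  subsets <- list()
  for (size in seq_len(n)) {
    cmb <- utils::combn(n, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  with_seed(seed, {
    scaff <- vapply(subsets, function(ix) {
      ix <- if (length(ix) > 1) sample(ix) else ix
      paste(fragments[ix], collapse = ".")
    }, "")
    data.frame(scaffold = scaff, molecule = molecule,
               subset_size = lengths(subsets),
               stringsAsFactors = FALSE)
  })
}

#' Build the full pair table for a molecule library
#'
#' Convenience wrapper: fragments every molecule and enumerates all
#' scaffold-molecule pairs.  Duplicate pairs arising from symmetric
#' molecules are kept (a logged count reports them).
#'
#' @param tbl Molecule table (column `smiles`).
#' @param seed Integer seed.
#' @param max_fragments Per-molecule fragment cap.
#' @param max_subset_size Optional cap on scaffold subset size (reduces the
#'   pair count from 2^n - 1 when training at small scale); `Inf` keeps all.
#' @return data.frame `scaffold`, `molecule`, `subset_size`.
#' @export
build_pair_table <- function(tbl, seed = 1L, max_fragments = 4L,
                             max_subset_size = Inf) {
  frs <- brics_leaf_fragments(tbl$smiles, max_fragments = max_fragments)
  out <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    if (is.null(frs[[i]])) next
    p <- enumerate_pairs(frs[[i]], tbl$smiles[i], seed = seed + i)
    if (is.finite(max_subset_size))
      p <- p[p$subset_size <= max_subset_size, , drop = FALSE]
    out[[i]] <- p
  }
  pairs <- do.call(rbind, out)
  ndup <- sum(duplicated(pairs[c("scaffold", "molecule")]))
  if (ndup > 0)
    scafgen_log("build_pair_table: %d duplicate pair(s) kept", ndup)
  rownames(pairs) <- NULL
  pairs
}

scaffold_key <- function(scaffold) {
  vapply(strsplit(scaffold, ".", fixed = TRUE),
         function(fr) paste(sort(fr), collapse = "."), "")
}

#' Scaffold-based 8:1:1 split
#'
#' Partitions the set of distinct scaffolds (identified by their sorted
#' fragment multiset, so fragment order never leaks across partitions)
#' into train/validation/test and assigns every pair to its scaffold's
#' partition.  Validation and test each receive ceiling(N/10) scaffolds;
#' the remainder goes to train.
#'
#' @param pairs Pair table from [build_pair_table()].
#' @param seed Integer seed (deterministic partition).
#' @return Named list `train`, `valid`, `test` of pair tables.
#' @export
scaffold_split <- function(pairs, seed = 1L) {
  key <- scaffold_key(pairs$scaffold)
  scaffolds <- unique(key)
  n <- length(scaffolds)
  if (n < 3) stop("need at least 3 distinct scaffolds to split, got ", n)
  n_valid <- ceiling(n / 10)
  n_test <- ceiling(n / 10)
  with_seed(seed, {
    perm <- sample(scaffolds)
    valid_s <- perm[seq_len(n_valid)]
    test_s <- perm[n_valid + seq_len(n_test)]
    part <- ifelse(key %in% valid_s, "valid",
                   ifelse(key %in% test_s, "test", "train"))
    list(train = pairs[part == "train", , drop = FALSE],
         valid = pairs[part == "valid", , drop = FALSE],
         test = pairs[part == "test", , drop = FALSE])
  })
}
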