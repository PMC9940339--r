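# Population-level evaluation of generated molecule sets: the five
# coefficients (validity, accuracy, desirability, uniqueness, novelty)
# and Solow-Polasky diversity.

#' Tanimoto distance between two fingerprints
#'
#' `d = 1 - |i & j| / |i | j|` on ECFP6 on-bit sets; two empty
#' fingerprints have distance 0 by convention.
#'
#' @param a,b Integer vectors of on-bit indices.
#' @return Distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Pairwise Tanimoto distance matrix
#' @param fps List of on-bit integer vectors.
#' @return Symmetric m x m matrix with zero diagonal.
#' @export
tanimoto_distance_matrix <- function(fps) {
  m <- length(fps)
  D <- matrix(0, m, m)
  if (m < 2) return(D)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      D[i, j] <- D[j, i] <- tanimoto_distance(fps[[i]], fps[[j]])
    }
  }
  D
}

#' Solow-Polasky diversity
#'
#' `I(A) = (1/m) e' F^-1 e` with kernel `F = [exp(-theta * d_ij)]` over
#' pairwise Tanimoto distances; the population-size normalization maps a
#' single molecule to 1 and `m` mutually maximally distant molecules
#' towards an effective number of distinct members per molecule.
#' Exact duplicates (distance-zero pairs make `F` singular) are collapsed
#' first, and `m` counts distinct structures.
#'
#' @param fps List of ECFP6 on-bit vectors (see [ecfp6_bits()]).
#' @param theta Kernel decay (default 0.5).
#' @return Diversity in (0, 1].
#' @export
solow_polasky_diversity <- function(fps, theta = 0.5) {
  stopifnot(length(fps) >= 1)
  key <- vapply(fps, function(b) paste(b, collapse = ","), "")
  fps <- fps[!duplicated(key)]
  m <- length(fps)
  if (m == 1) return(1)
  F <- exp(-theta * tanimoto_distance_matrix(fps))
  x <- tryCatch(solve(F, rep(1, m)), error = function(e)
    stop(sprintf("kernel matrix singular after deduplication (rcond = %.3g)",
                 rcond(F))))
  sum(x) / m
}

#' Scaffold containment
#'
#' A molecule contains a scaffold when every '.'-separated fragment is a
#' substructure match of its aromatic-perceived form.  A scaffold whose
#' grown molecule aromatized one of its bonds (e.g. 'CCC' grown into a
#' toluene-like ring, where a single bond became aromatic on
#' sanitization) therefore does not count as contained: the accuracy
#' coefficient reports this kekulization mismatch rather than hiding it.
#'
#' @param mols Character vector of molecule SMILES.
#' @param scaffolds Character vector ('.'-joined fragments), recycled to
#'   `length(mols)`.
#' @return Logical vector (`FALSE` for unparsable molecules).
#' @export
contains_scaffold <- function(mols, scaffolds) {
  n <- length(mols)
  scaffolds <- rep_len(scaffolds, n)
  ok <- !is.na(mols)
  out <- logical(n)
  if (!any(ok)) return(out)
  items <- mapply(function(m, s)
    list(mol = m, frags = as.list(strsplit(s, ".", fixed = TRUE)[[1]])),
    mols[ok], scaffolds[ok], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  res <- chem_call("match", items = items)
  out[ok] <- vapply(res$match, isTRUE, TRUE)
  out
}

#' Population metrics for a generated set
#'
#' Computes the five coefficients and Solow-Polasky diversity:
#' \describe{
#'   \item{validity}{fraction of outputs parsing as molecules}
#'   \item{accuracy}{fraction containing all fragments of their input
#'     scaffold}
#'   \item{desirability}{fraction with the desired flag set}
#'   \item{uniqueness}{fraction of distinct canonical structures}
#'   \item{novelty}{fraction of distinct structures absent from the
#'     reference set}
#' }
#'
#' @param generated data.frame with columns `scaffold` and `smiles`
#'   (raw generator output; `NA` = parse failure).
#' @param reference Character vector of canonical SMILES (the training
#'   corpus) used for novelty.
#' @param desired Optional logical vector (from [score_population()]);
#'   desirability is `NA` when absent.
#' @param theta Diversity kernel decay.
#' @return A `metrics_report` (list) with the six coefficients, `n_total`
#'   and the numerators.
#' @export
population_metrics <- function(generated, reference = character(0),
                               desired = NULL, theta = 0.5) {
  n_total <- nrow(generated)
  stopifnot(n_total >= 1)
  can <- rep(NA_character_, n_total)
  raw_ok <- !is.na(generated$smiles)
  if (any(raw_ok)) can[raw_ok] <- canonical_smiles(generated$smiles[raw_ok])
  valid <- !is.na(can)
  n_valid <- sum(valid)
  acc <- contains_scaffold(generated$smiles, generated$scaffold)
  n_accurate <- sum(acc)
  uniq <- unique(can[valid])
  n_unique <- length(uniq)
  n_novel <- length(setdiff(uniq, reference))
  n_desired <- if (is.null(desired)) NA_integer_ else sum(desired)
  diversity <- if (n_valid >= 1) {
    fps <- ecfp6_bits(uniq)
    fps <- fps[!vapply(fps, is.null, TRUE)]
    if (length(fps) >= 1) solow_polasky_diversity(fps, theta) else NA_real_
  } else NA_real_
  structure(list(
    n_total = n_total, n_valid = n_valid, n_accurate = n_accurate,
    n_desired = n_desired, n_unique = n_unique, n_novel = n_novel,
    validity = n_valid / n_total,
    accuracy = n_accurate / n_total,
    desirability = n_desired / n_total,
    uniqueness = n_unique / n_total,
    novelty = n_novel / n_total,
    diversity = diversity), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Population metrics (N = %d)\n",
    "  validity:     %6.1f%%\n",
    "  accuracy:     %6.1f%%\n",
    "  desirability: %6s\n",
    "  uniqueness:   %6.1f%%\n",
    "  novelty:      %6.1f%%\n",
    "  diversity:    %6.3f\n"),
    x$n_total, 100 * x$validity, 100 * x$accuracy,
    if (is.na(x$desirability)) "-" else sprintf("%.1f%%",
                                                100 * x$desirability),
    100 * x$uniqueness, 100 * x$novelty, x$diversity))
  invisible(x)
}
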