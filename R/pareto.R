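# Pareto dominance, non-dominated sorting, Tanimoto-based within-frontier
# ordering and the rank-based reward R*.
#
# Rewards: with 1-based global rank k, all undesired molecules ranked
# before all desired ones,
#
#   R* = k / (2 N_undesired)                        if undesired
#   R* = 0.5 + (k - N_undesired) / (2 N_desired)    if desired
#
# so undesired rewards are evenly spread over (0, 0.5] and desired rewards
# over (0.5, 1].  Within each group molecules are ordered worst frontier
# first, and inside a frontier by ascending mean Tanimoto distance to the
# other members: crowded molecules get smaller k, hence smaller reward,
# which promotes diversity.

#' Pareto dominance
#'
#' `x` dominates `y` iff `x_j >= y_j` for every objective and `x_j > y_j`
#' for at least one (all objectives oriented larger-is-better).
#'
#' @param x,y Numeric score vectors of equal length.
#' @return Logical.
#' @export
dominates <- function(x, y) {
  if (length(x) != length(y)) stop("score vectors differ in length")
  all(x >= y) && any(x > y)
}

#' Non-dominated sorting
#'
#' Frontier 1 is the set of solutions with no dominator in the population;
#' frontier f+1 is the non-dominated set after frontiers 1..f are removed.
#'
#' @param scores Numeric matrix, rows = solutions, columns = objectives
#'   (larger is better).
#' @return List of integer vectors (row indices), one per frontier; their
#'   union is the whole population.
#' @export
non_dominated_sort <- function(scores) {
  scores <- as.matrix(scores)
  N <- nrow(scores)
  if (N == 0) return(list())
  # dominance counts via pairwise comparison
  dom_count <- integer(N)          # number of solutions dominating i
  dominated_by <- vector("list", N) # solutions that i dominates
  for (i in seq_len(N)) {
    xi <- scores[i, ]
    for (j in seq_len(N)) {
      if (i == j) next
      xj <- scores[j, ]
      if (all(xj >= xi) && any(xj > xi)) dom_count[i] <- dom_count[i] + 1L
      else if (all(xi >= xj) && any(xi > xj))
        dominated_by[[i]] <- c(dominated_by[[i]], j)
    }
  }
  fronts <- list()
  current <- which(dom_count == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Order a frontier by mean Tanimoto distance
#'
#' Members are sorted ascending by their average Tanimoto distance to the
#' other members of the frontier (smallest -- most crowded -- first), with
#' deterministic ties broken by SMILES then index.
#'
#' @param idx Integer indices of the frontier members.
#' @param fps List of fingerprints (0-based on-bit integer vectors).
#' @param smiles Optional SMILES for tie-breaking.
#' @return `idx` reordered.
#' @export
order_within_frontier <- function(idx, fps, smiles = NULL) {
  if (length(idx) <= 1) return(idx)
  md <- vapply(seq_along(idx), function(a) {
    others <- idx[-a]
    mean(vapply(others, function(b)
      tanimoto_distance(fps[[idx[a]]], fps[[b]]), 0))
  }, 0)
  tie <- if (is.null(smiles)) rep("", length(idx)) else smiles[idx]
  idx[order(md, tie, idx)]
}

#' Pareto ranking of a scored population
#'
#' Combines non-dominated sorting, within-frontier Tanimoto ordering and
#' the undesired-before-desired convention into the global 1-based rank k.
#' Invalid molecules are treated as undesired and ranked below every valid
#' undesired molecule.
#'
#' @param scores Numeric matrix of objective scores (larger is better);
#'   rows of invalid molecules may hold worst-case values.
#' @param desired Logical vector.
#' @param fps Fingerprint list (as [ecfp6_bits()] returns); `NULL` entries
#'   are tolerated for invalid molecules.
#' @param smiles Optional SMILES for deterministic tie-breaks.
#' @param valid Logical vector (default all `TRUE`).
#' @return data.frame with `frontier` (NA for invalid molecules), `k`,
#'   `desired`, and attributes `n_desired` / `n_undesired`.
#' @export
pareto_ranking <- function(scores, desired, fps = NULL, smiles = NULL,
                           valid = NULL) {
  scores <- as.matrix(scores)
  N <- nrow(scores)
  stopifnot(length(desired) == N)
  if (is.null(valid)) valid <- rep(TRUE, N)
  desired <- desired & valid
  frontier <- rep(NA_integer_, N)
  vidx <- which(valid)
  ordered_v <- integer(0)
  if (length(vidx)) {
    fronts <- non_dominated_sort(scores[vidx, , drop = FALSE])
    for (f in seq_along(fronts)) {
      members <- vidx[fronts[[f]]]
      frontier[members] <- f
    }
    # worst frontier first; within a frontier, crowded first
    for (f in rev(seq_along(fronts))) {
      members <- vidx[fronts[[f]]]
      members <- if (is.null(fps)) {
        tie <- if (is.null(smiles)) rep("", length(members))
               else smiles[members]
        members[order(tie, members)]
      } else order_within_frontier(members, fps, smiles)
      ordered_v <- c(ordered_v, members)
    }
  }
  inv <- which(!valid)
  tie_inv <- if (is.null(smiles)) rep("", length(inv)) else smiles[inv]
  inv <- inv[order(tie_inv, inv)]
  und_v <- ordered_v[!desired[ordered_v]]
  des_v <- ordered_v[desired[ordered_v]]
  global <- c(inv, und_v, des_v)   # k = 1 is the worst molecule
  k <- integer(N)
  k[global] <- seq_len(N)
  out <- data.frame(frontier = frontier, k = k, desired = desired)
  attr(out, "n_desired") <- sum(desired)
  attr(out, "n_undesired") <- N - sum(desired)
  out
}

#' Rank-based rewards R*
#'
#' @param ranking Output of [pareto_ranking()].
#' @return Numeric vector of rewards in (0, 1]: undesired molecules in
#'   (0, 0.5], desired molecules in (0.5, 1].
#' @export
assign_rewards <- function(ranking) {
  k <- ranking$k
  des <- ranking$desired
  n_des <- attr(ranking, "n_desired")
  n_und <- attr(ranking, "n_undesired")
  r <- numeric(length(k))
  if (n_und > 0) r[!des] <- k[!des] / (2 * n_und)
  if (n_des > 0) r[des] <- 0.5 + (k[des] - n_und) / (2 * n_des)
  r
}
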