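# Objective scoring: descriptors, the affinity regressor, drug-likeness
# (QED), synthetic accessibility (SA, reported but never optimized), and
# the desired-molecule rule (predicted pX >= 6.5).

.physchem_names <- c("MW", "logP", "HBA", "HBD", "RotBonds", "AmideBonds",
                     "BridgeheadAtoms", "Heteroatoms", "SpiroAtoms",
                     "HeavyAtoms", "FractionCSP3", "AliphaticRings",
                     "SaturatedRings", "TotalRings", "AromaticRings",
                     "Heterocycles", "ValenceElectrons", "TPSA", "MR")

#' Compute molecular descriptors
#'
#' 2048-bit ECFP6 fingerprints (radius 3) followed by 19 physicochemical
#' descriptors: molecular weight, logP, H-bond acceptors/donors, rotatable
#' bonds, amide bonds, bridgehead atoms, heteroatoms, spiro atoms, heavy
#' atoms, fraction sp3 carbons, aliphatic/saturated/total/aromatic rings,
#' heterocycles, valence electrons, polar surface area and Wildman-Crippen
#' molar refractivity.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix, one row per molecule, 2067 columns; rows of
#'   unparsable molecules are `NA`.
#' @export
compute_descriptors <- function(smiles) {
  n <- length(smiles)
  out <- matrix(NA_real_, n, 2048 + 19,
                dimnames = list(NULL, c(sprintf("ecfp%04d", 1:2048),
                                        .physchem_names)))
  if (n == 0) return(out)
  res <- chem_call("descriptors", smiles = as.list(as.character(smiles)))
  for (i in seq_len(n)) {
    d <- res$descriptors[[i]]
    if (is.null(d)) next
    fp <- numeric(2048)
    fp[as.integer(unlist(d$bits)) + 1L] <- 1
    out[i, ] <- c(fp, as.numeric(unlist(d$physchem)))
  }
  out
}

#' Train the affinity regressor
#'
#' Fits a random-forest regression of pX on [compute_descriptors()]
#' features (500 trees by default).  The model predicts the activity
#' objective during scoring and reinforcement learning.
#'
#' @param tbl Molecule table with finite `pX` for at least 25 rows.
#' @param ntree Number of trees.
#' @param seed RNG seed (reproducible predictions).
#' @return An `affinity_model` object.
#' @export
train_affinity_model <- function(tbl, ntree = 500L, seed = 1L) {
  keep <- is.finite(tbl$pX)
  if (sum(keep) < 25) stop("need at least 25 molecules with finite pX")
  y <- tbl$pX[keep]
  if (stats::sd(y) < 1e-9) stop("constant pX values; nothing to learn")
  X <- compute_descriptors(tbl$smiles[keep])
  ok <- stats::complete.cases(X)
  rf <- with_seed(seed, randomForest::randomForest(X[ok, , drop = FALSE],
                                                   y[ok], ntree = ntree))
  structure(list(rf = rf, n = sum(ok), schema = ncol(X)),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model: random forest, %d trees, %d molecules>\n",
              x$rf$ntree, x$n))
  invisible(x)
}

#' Predict activity for molecules
#'
#' @param object An `affinity_model`.
#' @param smiles SMILES vector, or a precomputed descriptor matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted pX (`NA` for unparsable molecules).
#' @export
predict.affinity_model <- function(object, smiles, ...) {
  X <- if (is.matrix(smiles)) smiles else compute_descriptors(smiles)
  out <- rep(NA_real_, nrow(X))
  ok <- stats::complete.cases(X)
  if (any(ok))
    out[ok] <- stats::predict(object$rf, X[ok, , drop = FALSE])
  out
}

#' Score a generated population
#'
#' Computes QED, SA and predicted affinity per molecule and sets the
#' desired flag: affinity at or above `activity_threshold` (pX 6.5, i.e.
#' ~316 nM), optionally also requiring QED at or above `qed_cutoff` when a
#' cutoff is configured.  Unparsable molecules get worst-case scores (qed
#' 0, sa 10, affinity NA) and `desired = FALSE`.
#'
#' @param smiles Character vector of SMILES (possibly invalid).
#' @param model An `affinity_model`, or any function mapping a SMILES
#'   vector to predicted pX values (the scorer interface is pluggable);
#'   required when `"affinity"` is among the objectives.
#' @param objectives Character subset of `c("affinity", "qed")`; the score
#'   columns entering Pareto ranking.
#' @param activity_threshold Desired-molecule threshold on predicted pX.
#' @param qed_cutoff Optional QED requirement for the desired flag
#'   (disabled by default: desirability follows the affinity score alone).
#' @return data.frame `smiles`, `valid`, `qed`, `sa`, `affinity`,
#'   `desired`, plus attribute `"objectives"` naming the score columns.
#' @export
score_population <- function(smiles, model = NULL,
                             objectives = c("affinity", "qed"),
                             activity_threshold = 6.5, qed_cutoff = NULL) {
  objectives <- match.arg(objectives, c("affinity", "qed"),
                          several.ok = TRUE)
  if ("affinity" %in% objectives && is.null(model))
    stop("an affinity model is required when affinity is an objective")
  n <- length(smiles)
  out <- data.frame(smiles = as.character(smiles), valid = FALSE,
                    qed = 0, sa = 10, affinity = NA_real_,
                    desired = FALSE, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  parse_ok <- !is.na(smiles)
  if (any(parse_ok)) {
    qs <- chem_call("score", smiles = as.list(smiles[parse_ok]))$scores
    got <- !vapply(qs, is.null, TRUE)
    out$valid[parse_ok] <- got
    out$qed[parse_ok][got] <- vapply(qs[got], function(x) x$qed, 0)
    out$sa[parse_ok][got] <- vapply(qs[got], function(x) x$sa, 0)
  }
  if (!is.null(model) && any(out$valid)) {
    out$affinity[out$valid] <-
      if (is.function(model)) model(out$smiles[out$valid])
      else predict(model, out$smiles[out$valid])
  }
  des <- out$valid & !is.na(out$affinity) &
    out$affinity >= activity_threshold
  if (!is.null(qed_cutoff)) des <- des & out$qed >= qed_cutoff
  out$desired <- des
  attr(out, "objectives") <- objectives
  out
}
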