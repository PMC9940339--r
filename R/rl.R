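# Policy-gradient reinforcement learning with a frozen exploration net.
#
# Objective: J(theta) = E[R*(y_1:T)] approximated by REINFORCE -- every
# sampled decision's log-probability is weighted by the episode's terminal
# Pareto-rank reward.  An exploitation net G_theta is updated each epoch;
# a frozen exploration net G_phi answers a fraction epsilon of the scaffold
# inputs to keep the sampled chemistry broad, and is discarded afterwards.

#' Reinforcement-learning configuration
#'
#' @param epsilon Exploring rate in `[0, 1]`: fraction of scaffold inputs
#'   answered by the frozen exploration net.
#' @param epochs Training epochs.
#' @param batch Scaffolds sampled (with replacement) per epoch.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return An `rl_config` list.
#' @export
rl_config <- function(epsilon = 0.1, epochs = 30L, batch = 64L, lr = 1e-4,
                      seed = 1L) {
  if (epsilon < 0 || epsilon > 1)
    stop("epsilon must lie in [0, 1], got ", epsilon)
  structure(list(epsilon = epsilon, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr,
                 seed = as.integer(seed)),
            class = "rl_config")
}

# episodes (sampling output with attached tensors) -> training batch
episode_batch <- function(model, episodes) {
  if (is_graph_kind(model$kind)) {
    batch <- graph_prep(attr(episodes, "matrices"), model$vocab,
                        model$gc$max_len)
    batch$masks <- attr(episodes, "masks")
    batch
  } else {
    toks <- attr(episodes, "tokens")
    list(enc = attr(episodes, "enc"),
         dec_in = toks[, -ncol(toks), drop = FALSE],
         target = toks[, -1, drop = FALSE])
  }
}

#' One policy-gradient update
#'
#' Recomputes the stepwise log-probabilities of the sampled episodes under
#' the current agent (for the graph model all four per-step decisions
#' contribute) and ascends the reward-weighted likelihood.  Batches with a
#' non-finite loss are skipped with a warning.
#'
#' @param model The agent (`scafgen_generator`), updated in place.
#' @param episodes Output of [sample_molecules()] (episode tensors
#'   attached).
#' @param rewards Numeric rewards in (0, 1], one per episode.
#' @param opt Adam state from `adam_init(model$params)`.
#' @param lr Learning rate.
#' @return Updated Adam state.
#' @export
policy_gradient_step <- function(model, episodes, rewards, opt, lr = 1e-4) {
  batch <- episode_batch(model, episodes)
  loss <- generator_loss(model, batch, pg_weights = rewards)
  lv <- ad_val(loss)[1]
  if (!is.finite(lv)) {
    warning("non-finite policy-gradient loss; batch skipped")
    ad_zero_grads(model$params)
    return(opt)
  }
  ad_backward(loss)
  adam_step(opt, model$params, lr = lr)
}

#' Multi-objective reinforcement learning
#'
#' Each epoch a batch of scaffolds is drawn from the pool; a fraction
#' `cfg$epsilon` is answered by the frozen exploration net and the rest by
#' the agent.  All generated molecules are scored, Pareto-ranked and
#' rewarded, and only the agent's parameters are updated.  The exploration
#' net is left bit-identical.
#'
#' @param agent Exploitation net G_theta (updated in place and returned).
#' @param frozen Exploration net G_phi (same architecture and vocabulary),
#'   or `NULL` to disable exploration regardless of epsilon.
#' @param scaffolds Character vector: the scaffold pool.
#' @param affinity An `affinity_model` for the activity objective.
#' @param cfg An [rl_config()].
#' @param objectives Score columns entering Pareto ranking
#'   (subset of `c("affinity", "qed")`).
#' @param qed_cutoff Optional QED requirement for the desired flag.
#' @param reference Canonical SMILES of the training corpus (for the
#'   novelty column of the per-epoch metrics; optional).
#' @return List with `agent` and `metrics` (per-epoch data.frame: epoch,
#'   desirability, uniqueness, diversity, mean_reward).
#' @export
rl_train <- function(agent, frozen, scaffolds, affinity, cfg = rl_config(),
                     objectives = c("affinity", "qed"), qed_cutoff = NULL,
                     reference = character(0)) {
  stopifnot(length(scaffolds) >= 1)
  if (!is.null(frozen) && !identical(frozen$kind, agent$kind))
    stop("agent and exploration net must share an architecture")
  opt <- adam_init(agent$params)
  metrics <- data.frame()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      pool <- sample(scaffolds, cfg$batch, replace = TRUE)
      n_phi <- if (is.null(frozen)) 0L else round(cfg$epsilon * cfg$batch)
      seeds <- sample.int(1e6, 2)
      eps_theta <- sample_molecules(agent, pool[seq_len(cfg$batch - n_phi)],
                                    k = 1L, seed = seeds[1])
      eps_all <- eps_theta
      if (n_phi > 0) {
        eps_phi <- sample_molecules(frozen,
                                    pool[cfg$batch - n_phi + seq_len(n_phi)],
                                    k = 1L, seed = seeds[2])
        eps_all <- rbind(eps_theta, eps_phi)
        if (is_graph_kind(agent$kind)) {
          attr(eps_all, "matrices") <- c(attr(eps_theta, "matrices"),
                                         attr(eps_phi, "matrices"))
          attr(eps_all, "masks") <- c(attr(eps_theta, "masks"),
                                      attr(eps_phi, "masks"))
        } else {
          pad <- function(m, w) cbind(m, matrix(0L, nrow(m), w - ncol(m)))
          w_enc <- max(ncol(attr(eps_theta, "enc")),
                       ncol(attr(eps_phi, "enc")))
          w_tok <- max(ncol(attr(eps_theta, "tokens")),
                       ncol(attr(eps_phi, "tokens")))
          attr(eps_all, "enc") <- rbind(pad(attr(eps_theta, "enc"), w_enc),
                                        pad(attr(eps_phi, "enc"), w_enc))
          attr(eps_all, "tokens") <-
            rbind(pad(attr(eps_theta, "tokens"), w_tok),
                  pad(attr(eps_phi, "tokens"), w_tok))
        }
      }
      sc <- score_population(eps_all$smiles, affinity,
                             objectives = objectives,
                             qed_cutoff = qed_cutoff)
      smat <- as.matrix(sc[, objectives, drop = FALSE])
      smat[is.na(smat)] <- 0
      fps <- vector("list", nrow(sc))
      if (any(sc$valid)) fps[sc$valid] <- ecfp6_bits(sc$smiles[sc$valid])
      rank <- pareto_ranking(smat, sc$desired, fps, sc$smiles, sc$valid)
      rew <- assign_rewards(rank)
      opt <- policy_gradient_step(agent, eps_all, rew, opt, lr = cfg$lr)
      can <- ifelse(sc$valid, sc$smiles, NA_character_)
      uniq <- unique(can[!is.na(can)])
      div <- if (length(uniq) >= 1) {
        ufps <- fps[match(uniq, can)]
        ufps <- ufps[!vapply(ufps, is.null, TRUE)]
        if (length(ufps)) solow_polasky_diversity(ufps) else NA_real_
      } else NA_real_
      metrics <- rbind(metrics, data.frame(
        epoch = epoch,
        desirability = mean(sc$desired),
        uniqueness = length(uniq) / nrow(sc),
        novelty = length(setdiff(uniq, reference)) / nrow(sc),
        diversity = div,
        mean_reward = mean(rew)))
    }
  })
  list(agent = agent, metrics = metrics)
}
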