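# The four encoder-decoder generator architectures, their shared training
# loop, and scaffold-conditioned sampling.
#
#   graph-transformer : five-row graph matrices; transformer encoder over
#                       the fragment section, causal transformer decoder
#                       over growing/linking columns, and a GRU head that
#                       decodes the four per-column decisions (atom type,
#                       bond type, connected index, current index) one by
#                       one.  Sampling applies the valence mask at every
#                       decision, so every emission decodes to a molecule.
#   seq-transformer   : token-level transformer encoder-decoder on SMILES.
#   lstm-base         : stacked-LSTM encoder-decoder; the encoder's final
#                       hidden/cell states initialize the decoder.
#   lstm-attn         : lstm-base plus dot-product attention over encoder
#                       outputs, concatenated with the decoder embedding.

#' Generator architecture configuration
#'
#' @param kind One of `"graph-transformer"`, `"seq-transformer"`,
#'   `"lstm-base"`, `"lstm-attn"`.
#' @param d_model Transformer model width (default 512).
#' @param heads Attention heads (default 8; `d_model` must be divisible).
#' @param n_layers Encoder and decoder depth (default 3).
#' @param d_ff Feed-forward width (default `4 * d_model`).
#' @param emb Embedding size of the LSTM models (default 128).
#' @param hidden Hidden size of the LSTM models (default 512).
#' @param rec_layers Recurrent layers in the LSTM models (default 3).
#' @param max_len Maximum sequence length / graph-matrix width.
#' @return A `generator_config` list.
#' @export
generator_config <- function(kind = c("graph-transformer", "seq-transformer",
                                      "lstm-base", "lstm-attn"),
                             d_model = 512L, heads = 8L, n_layers = 3L,
                             d_ff = 4L * d_model, emb = 128L, hidden = 512L,
                             rec_layers = 3L,
                             max_len = if (kind == "graph-transformer") 80L
                                       else 100L) {
  kind <- match.arg(kind)
  stopifnot(d_model %% heads == 0, max_len > 4)
  structure(list(kind = kind, d_model = as.integer(d_model),
                 heads = as.integer(heads), n_layers = as.integer(n_layers),
                 d_ff = as.integer(d_ff), emb = as.integer(emb),
                 hidden = as.integer(hidden),
                 rec_layers = as.integer(rec_layers),
                 max_len = as.integer(max_len)),
            class = "generator_config")
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 256).
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience: training halts once the
#'   validation loss has not improved for this many epochs (default 100).
#' @param seed RNG seed for shuffling and initialisation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 256L, epochs = 20L,
                         patience = 100L, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, patience >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

is_graph_kind <- function(kind) identical(kind, "graph-transformer")

#' Initialize a generator
#'
#' @param kind Architecture kind (see [generator_config()]).
#' @param vocab A [smiles_vocab()] (sequence kinds) or [graph_vocab()].
#' @param gc A [generator_config()].
#' @param seed Seed for weight initialisation.
#' @return A `scafgen_generator` object.
#' @export
new_generator <- function(kind, vocab, gc = generator_config(kind),
                          seed = 1L) {
  stopifnot(identical(gc$kind, kind))
  V <- length(vocab$tokens)
  d <- gc$d_model
  with_seed(seed, {
    p <- list()
    if (kind == "graph-transformer") {
      p$Wemb <- .init_mat(V * 4L, d)
      p <- c(p, transformer_params("enc", gc$n_layers, d, gc$d_ff),
             transformer_params("dec", gc$n_layers, d, gc$d_ff, cross = TRUE),
             gru_params("gru", d, d))
      p$EA <- .init_mat(V, d)
      p$EB <- .init_mat(4L, d)
      p$EP <- .init_mat(gc$max_len, d)
      p$W_atom <- .init_mat(d, V); p$b_atom <- .init_zero(V)
      p$W_bond <- .init_mat(d, 4L); p$b_bond <- .init_zero(4L)
      p$W_conn <- .init_mat(d, gc$max_len); p$b_conn <- .init_zero(gc$max_len)
      p$W_curr <- .init_mat(d, gc$max_len); p$b_curr <- .init_zero(gc$max_len)
    } else if (kind == "seq-transformer") {
      p$Etok <- .init_mat(V, d)
      p <- c(p, transformer_params("enc", gc$n_layers, d, gc$d_ff),
             transformer_params("dec", gc$n_layers, d, gc$d_ff, cross = TRUE))
      p$W_out <- .init_mat(d, V); p$b_out <- .init_zero(V)
    } else {
      H <- gc$hidden
      p$Etok <- .init_mat(V, gc$emb)
      p <- c(p, lstm_params("enc", gc$rec_layers, gc$emb, H))
      dec_in <- if (kind == "lstm-attn") gc$emb + H else gc$emb
      p <- c(p, lstm_params("dec", gc$rec_layers, dec_in, H))
      if (kind == "lstm-attn") p$Wa <- .init_mat(H, H)
      p$W_out <- .init_mat(H, V); p$b_out <- .init_zero(V)
    }
    structure(list(kind = kind, vocab = vocab, gc = gc, params = p),
              class = "scafgen_generator")
  })
}

#' @export
print.scafgen_generator <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$val), 0))
  cat(sprintf("<scafgen_generator: %s, %s parameters>\n", x$kind,
              format(np, big.mark = ",")))
  invisible(x)
}

generator_snapshot <- function(model) lapply(model$params, function(p) p$val)

generator_restore <- function(model, snap) {
  for (nm in names(snap)) model$params[[nm]]$val <- snap[[nm]]
  invisible(model)
}

#' Checksum of a generator's parameters (used to verify frozen nets)
#' @param model A `scafgen_generator`.
#' @return A single numeric hash-like value.
#' @export
generator_checksum <- function(model) {
  sum(vapply(model$params, function(p) sum(p$val * seq_along(p$val)), 0))
}

# ---------------------------------------------------------------------------
# Tensor preparation

# sequence pairs -> 0-based id matrices, trimmed to the longest row
seq_prep <- function(pairs, vocab, L) {
  enc <- encode_smiles_pairs(pairs, vocab, L)
  trim <- function(m) {
    used <- which(colSums(m != 0) > 0)
    m[, seq_len(max(used)), drop = FALSE]
  }
  inp <- trim(enc$input); out <- trim(enc$output)
  list(enc = inp, dec_in = out[, -ncol(out), drop = FALSE],
       target = out[, -1, drop = FALSE], kept = enc$kept)
}

# graph matrices -> encoder (fragment section) and decoder tensors
graph_prep <- function(mats, vocab, L) {
  B <- length(mats)
  eos <- vocab$index[["EOS"]]
  encs <- vector("list", B); decs <- vector("list", B)
  for (i in seq_len(B)) {
    m <- mats[[i]]
    fcols <- which(m["frag", ] > 0)
    esel <- c(1L, fcols)                      # GO + fragment section
    eos_cols <- which(m["atom", ] == eos)
    last <- eos_cols[2]                       # terminal EOS column
    dsel <- setdiff(seq_len(last), esel)
    encs[[i]] <- m[, esel, drop = FALSE]
    decs[[i]] <- m[, dsel, drop = FALSE]
  }
  Fmax <- max(vapply(encs, ncol, 0L))
  Tmax <- max(vapply(decs, ncol, 0L))
  pad_ids <- function(blocks, width, row_fn) {
    t(vapply(blocks, function(bk) {
      v <- row_fn(bk)
      c(v, rep(0L, width - length(v)))
    }, integer(width)))
  }
  word <- function(bk) bk["atom", ] * 4L + bk["bond", ]
  posi <- function(bk) bk["curr", ] * L + bk["conn", ]
  enc_w <- pad_ids(encs, Fmax, word)
  enc_p <- pad_ids(encs, Fmax, posi)
  enc_mask <- t(vapply(encs, function(bk)
    c(rep(TRUE, ncol(bk)), rep(FALSE, Fmax - ncol(bk))), logical(Fmax)))
  dec_w <- pad_ids(decs, Tmax, word)
  dec_p <- pad_ids(decs, Tmax, posi)
  tg <- function(row) pad_ids(decs, Tmax, function(bk) bk[row, ])
  wts <- t(vapply(decs, function(bk)
    c(rep(1, ncol(bk)), rep(0, Tmax - ncol(bk))), numeric(Tmax)))
  # decoder inputs: GO word at t = 1, then columns shifted right
  go_w <- vocab$index[["GO"]] * 4L
  dec_in_w <- cbind(go_w, dec_w[, -Tmax, drop = FALSE])
  dec_in_p <- cbind(0L, dec_p[, -Tmax, drop = FALSE])
  list(enc_w = enc_w, enc_p = enc_p, enc_mask = enc_mask,
       dec_in_w = dec_in_w, dec_in_p = dec_in_p,
       t_atom = tg("atom"), t_bond = tg("bond"),
       t_conn = tg("conn"), t_curr = tg("curr"), weights = wts)
}

# ---------------------------------------------------------------------------
# Forward passes (return row-stacked decoder hidden states or logits)

.stack_ids <- function(m) as.vector(t(m)) + 1L   # B x L -> (B*L), 1-based

.fwd_seq_transformer <- function(model, enc_ids, dec_ids, rows = NULL) {
  p <- model$params; gc <- model$gc
  B <- nrow(enc_ids); Le <- ncol(enc_ids); Ld <- ncol(dec_ids)
  pe_e <- positional_encoding(0:(Le - 1), gc$d_model)
  pe_d <- positional_encoding(0:(Ld - 1), gc$d_model)
  x <- ad_add(ad_rows(p$Etok, .stack_ids(enc_ids)),
              pe_e[rep(seq_len(Le), B), , drop = FALSE])
  enc_mask <- enc_ids != 0L
  eo <- tf_encode(x, p, gc$n_layers, B, Le, gc$heads, enc_mask)
  y <- ad_add(ad_rows(p$Etok, .stack_ids(dec_ids)),
              pe_d[rep(seq_len(Ld), B), , drop = FALSE])
  h <- tf_decode(y, eo, p, gc$n_layers, B, Ld, Le, gc$heads, enc_mask)
  if (!is.null(rows)) h <- ad_slice_rows(h, rows)
  ad_add(ad_matmul(h, p$W_out), p$b_out)
}

.fwd_lstm <- function(model, enc_ids, dec_ids, rows = NULL) {
  p <- model$params; gc <- model$gc
  B <- nrow(enc_ids); Le <- ncol(enc_ids); Ld <- ncol(dec_ids)
  H <- gc$hidden
  xs <- lapply(seq_len(Le), function(t)
    ad_rows(p$Etok, enc_ids[, t] + 1L))
  er <- lstm_run(xs, p, "enc", gc$rec_layers, H, B)
  attn <- identical(model$kind, "lstm-attn")
  enc_stack <- if (attn) do.call(ad_rbind, er$outputs) else NULL
  # enc_stack rows are grouped by time; regroup by sample for attention
  if (attn) {
    ord <- as.vector(vapply(seq_len(B), function(b)
      (seq_len(Le) - 1L) * B + b, integer(Le)))
    enc_stack <- ad_slice_rows(enc_stack, ord)
    enc_mask <- enc_ids != 0L
  }
  hs <- er$h; cs <- er$c
  outs <- vector("list", Ld)
  for (t in seq_len(Ld)) {
    emb <- ad_rows(p$Etok, dec_ids[, t] + 1L)
    x <- if (attn) {
      q <- ad_matmul(hs[[gc$rec_layers]], p$Wa)
      ctx <- ad_attention(q, enc_stack, enc_stack, B, 1L, Le, 1L,
                          mask = enc_mask)
      ad_cbind(emb, ctx)
    } else emb
    for (l in seq_len(gc$rec_layers)) {
      st <- .lstm_step(x, hs[[l]], cs[[l]], p, "dec", l)
      hs[[l]] <- st$h; cs[[l]] <- st$c
      x <- st$h
    }
    outs[[t]] <- x
  }
  h <- do.call(ad_rbind, outs)
  # rows grouped by time; regroup by sample
  ord <- as.vector(vapply(seq_len(B), function(b)
    (seq_len(Ld) - 1L) * B + b, integer(Ld)))
  h <- ad_slice_rows(h, ord)
  if (!is.null(rows)) h <- ad_slice_rows(h, rows)
  ad_add(ad_matmul(h, p$W_out), p$b_out)
}

# incremental decoder for sampling: precomputes the encoder stack and
# per-layer cross-attention projections, then advances one column at a
# time with cached self-attention keys/values (plain matrices, no tape).
# Exactly mirrors .fwd_graph_trunk / .tf_layer post-LN arithmetic.
.graph_decoder_stepper <- function(model, enc_w, enc_p, enc_mask, Tcap) {
  p <- model$params; gcfg <- model$gc
  B <- nrow(enc_w); Le <- ncol(enc_w)
  d <- gcfg$d_model; heads <- gcfg$heads; nl <- gcfg$n_layers
  dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  pv <- lapply(p, function(x) x$val)
  ln <- function(x, g, b, eps = 1e-5) {
    mu <- rowMeans(x)
    xc <- x - mu
    inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
    sweep(sweep(xc * inv, 2, g, "*"), 2, b, "+")
  }
  nm <- function(l, s) pv[[sprintf("dec_l%d_%s", l, s)]]
  eo <- ad_no_grad(ad_val(tf_encode(
    pv$Wemb[as.vector(t(enc_w)) + 1L, , drop = FALSE] +
      positional_encoding(as.vector(t(enc_p)), d),
    p, nl, B, Le, heads, enc_mask)))
  # caches are step-major: row (s-1)*B + b holds step s of sample b, so a
  # whole step's attention is a handful of C-level ops over all samples
  step_major <- as.vector(vapply(seq_len(Le), function(s)
    (seq_len(B) - 1L) * Le + s, integer(B)))
  crossK <- lapply(seq_len(nl), function(l)
    (eo %*% nm(l, "Xk"))[step_major, , drop = FALSE])
  crossV <- lapply(seq_len(nl), function(l)
    (eo %*% nm(l, "Xv"))[step_major, , drop = FALSE])
  pen_cross <- as.vector(ifelse(enc_mask, 0, -1e30))  # row (s-1)*B + b
  selfK <- lapply(seq_len(nl), function(l) matrix(0, B * Tcap, d))
  selfV <- lapply(seq_len(nl), function(l) matrix(0, B * Tcap, d))
  colhead <- rep(seq_len(heads), each = dk)
  Hmask <- outer(colhead, seq_len(heads), "==") * 1   # d x heads
  # batched one-step multi-head attention of q (B x d) against the first
  # t steps of a step-major K/V cache; pen is a (t*B)-vector or NULL.
  # scores are clamped to +-30 before exponentiation: masked positions
  # stay negligible and no group can underflow to an all-zero softmax
  att_step <- function(q, Kc, Vc, t, pen = NULL) {
    n <- t * B
    qe <- q[rep(seq_len(B), t), , drop = FALSE]
    S <- ((Kc[seq_len(n), , drop = FALSE] * qe) %*% Hmask) * scale
    if (!is.null(pen)) S <- S + pen
    S <- exp(pmin(pmax(S, -30), 30))
    groups <- rep(seq_len(B), t)
    D <- rowsum(S, groups, reorder = TRUE)              # B x heads
    P <- Vc[seq_len(n), , drop = FALSE] * S[, colhead, drop = FALSE]
    rowsum(P, groups, reorder = TRUE) / D[, colhead, drop = FALSE]
  }
  t_now <- 0L
  function(new_w, new_p) {
    t_now <<- t_now + 1L
    x <- pv$Wemb[new_w + 1L, , drop = FALSE] +
      positional_encoding(new_p, d)
    for (l in seq_len(nl)) {
      q <- x %*% nm(l, "Wq")
      rows_now <- (t_now - 1L) * B + seq_len(B)
      selfK[[l]][rows_now, ] <<- x %*% nm(l, "Wk")
      selfV[[l]][rows_now, ] <<- x %*% nm(l, "Wv")
      a <- att_step(q, selfK[[l]], selfV[[l]], t_now)
      x <- ln(x + a %*% nm(l, "Wo"), nm(l, "ln1_g"), nm(l, "ln1_b"))
      q2 <- x %*% nm(l, "Xq")
      a2 <- att_step(q2, crossK[[l]], crossV[[l]], Le, pen_cross)
      x <- ln(x + a2 %*% nm(l, "Xo"), nm(l, "ln2_g"), nm(l, "ln2_b"))
      f <- pmax(sweep(x %*% nm(l, "W1"), 2, nm(l, "b1"), "+"), 0) %*%
        nm(l, "W2")
      f <- sweep(f, 2, nm(l, "b2"), "+")
      x <- ln(x + f, nm(l, "ln3_g"), nm(l, "ln3_b"))
    }
    x
  }
}

# graph transformer trunk: returns decoder hidden states, (B*T) x d
.fwd_graph_trunk <- function(model, enc_w, enc_p, enc_mask, dec_w, dec_p) {
  p <- model$params; gc <- model$gc
  B <- nrow(enc_w); Le <- ncol(enc_w); Ld <- ncol(dec_w)
  d <- gc$d_model
  x <- ad_add(ad_rows(p$Wemb, .stack_ids(enc_w)),
              positional_encoding(as.vector(t(enc_p)), d))
  eo <- tf_encode(x, p, gc$n_layers, B, Le, gc$heads, enc_mask)
  y <- ad_add(ad_rows(p$Wemb, .stack_ids(dec_w)),
              positional_encoding(as.vector(t(dec_p)), d))
  tf_decode(y, eo, p, gc$n_layers, B, Ld, Le, gc$heads, enc_mask)
}

# the four-decision GRU head, teacher-forced on targets
.fwd_graph_head <- function(model, h, t_atom, t_bond, t_conn) {
  p <- model$params
  s0 <- h
  atom_logits <- ad_add(ad_matmul(s0, p$W_atom), p$b_atom)
  s1 <- gru_step(ad_rows(p$EA, as.vector(t(t_atom)) + 1L), s0, p, "gru")
  bond_logits <- ad_add(ad_matmul(s1, p$W_bond), p$b_bond)
  s2 <- gru_step(ad_rows(p$EB, as.vector(t(t_bond)) + 1L), s1, p, "gru")
  conn_logits <- ad_add(ad_matmul(s2, p$W_conn), p$b_conn)
  s3 <- gru_step(ad_rows(p$EP, as.vector(t(t_conn)) + 1L), s2, p, "gru")
  curr_logits <- ad_add(ad_matmul(s3, p$W_curr), p$b_curr)
  list(atom = atom_logits, bond = bond_logits,
       conn = conn_logits, curr = curr_logits)
}

# ---------------------------------------------------------------------------
# Loss

# batch: list of prepared tensors (seq_prep / graph_prep output subsets)
# pg_weights: per-sequence rewards for policy-gradient mode (NULL = NLL)
generator_loss <- function(model, batch, pg_weights = NULL) {
  if (is_graph_kind(model$kind)) {
    h <- .fwd_graph_trunk(model, batch$enc_w, batch$enc_p, batch$enc_mask,
                          batch$dec_in_w, batch$dec_in_p)
    lg <- .fwd_graph_head(model, h, batch$t_atom, batch$t_bond, batch$t_conn)
    w <- as.vector(t(batch$weights))
    tgt <- list(atom = batch$t_atom, bond = batch$t_bond,
                conn = batch$t_conn, curr = batch$t_curr)
    if (is.null(pg_weights)) {
      parts <- mapply(function(lgt, tg)
        ad_ce_loss(lgt, as.vector(t(tg)) + 1L, w),
        lg, tgt, SIMPLIFY = FALSE)
    } else {
      # REINFORCE: weight each stepwise log-probability by the episode
      # reward.  Only genuinely stochastic decisions contribute (forced or
      # single-option steps carry weight 0), and the sampling-time valence
      # masks are re-applied so the log-probabilities match the
      # distributions actually sampled from.
      Tm <- ncol(batch$t_atom); B <- nrow(batch$t_atom)
      rw_base <- rep(pg_weights, each = Tm) / length(pg_weights)
      mk <- batch$masks
      heads <- c("atom", "bond", "conn", "curr")
      parts <- vector("list", 4)
      for (hi in seq_along(heads)) {
        hd <- heads[hi]
        lgt <- lg[[hd]]
        V <- ncol(ad_val(lgt))
        sto <- matrix(0, B, Tm)
        if (!is.null(mk)) {
          pen <- matrix(0, B * Tm, V)
          for (b in seq_len(B)) {
            steps <- mk[[b]]
            for (t in seq_along(steps)) {
              allowed <- steps[[t]][[hd]]
              if (length(allowed) > 1) {
                sto[b, t] <- 1
                row <- (b - 1L) * Tm + t
                pen[row, ] <- -1e30
                pen[row, allowed + 1L] <- 0
              }
            }
          }
          lgt <- ad_add(lgt, pen)
        } else sto[] <- 1
        parts[[hi]] <- ad_pg_loss(lgt, as.vector(t(tgt[[hd]])) + 1L,
                                  w * as.vector(t(sto)) * rw_base)
      }
    }
    ad_add(ad_add(parts[[1]], parts[[2]]), ad_add(parts[[3]], parts[[4]]))
  } else {
    fwd <- if (model$kind == "seq-transformer") .fwd_seq_transformer
           else .fwd_lstm
    logits <- fwd(model, batch$enc, batch$dec_in)
    tgt <- as.vector(t(batch$target)) + 1L
    w <- as.numeric(as.vector(t(batch$target)) != 0L)
    if (is.null(pg_weights)) {
      ad_ce_loss(logits, tgt, w)
    } else {
      # the sequence sampler bans the padding and GO tokens; re-apply
      pen <- matrix(0, nrow(ad_val(logits)), ncol(ad_val(logits)))
      pen[, 1:2] <- -1e30
      Tm <- ncol(batch$target)
      ad_pg_loss(ad_add(logits, pen), tgt,
                 w * rep(pg_weights, each = Tm) / length(pg_weights))
    }
  }
}

.subset_batch <- function(prep, ix, graph) {
  if (graph) {
    lapply(prep, function(m) m[ix, , drop = FALSE])
  } else {
    list(enc = prep$enc[ix, , drop = FALSE],
         dec_in = prep$dec_in[ix, , drop = FALSE],
         target = prep$target[ix, , drop = FALSE])
  }
}

#' Train a generator by teacher-forced negative log-likelihood
#'
#' Minimizes the token-level NLL of the molecule given the scaffold (for
#' the graph model, the summed NLL of the four per-step decisions) with
#' Adam.  The best parameter snapshot is the epoch with minimum validation
#' loss; training stops early once the validation loss has not improved
#' for `tc$patience` epochs.
#'
#' @param model A [new_generator()] object (updated in place and returned).
#' @param train,valid Pair tables (`scaffold`, `molecule`) -- or, for the
#'   graph kind, these are encoded internally via [encode_graphs()].
#' @param tc A [train_config()].
#' @param quiet Suppress per-epoch log lines.
#' @return The model, with `$trace` (epoch, train_nll, valid_nll),
#'   `$best_epoch` and best-validation parameters restored.
#' @export
train_generator <- function(model, train, valid, tc = train_config(),
                            quiet = FALSE) {
  gc <- model$gc
  graph <- is_graph_kind(model$kind)
  prep_pairs <- function(pairs) {
    if (graph) {
      items <- lapply(seq_len(nrow(pairs)), function(i)
        list(molecule = pairs$molecule[i],
             frags = strsplit(pairs$scaffold[i], ".", fixed = TRUE)[[1]]))
      mats <- encode_graphs(items, model$vocab, gc$max_len)
      mats <- mats[!vapply(mats, is.null, TRUE)]
      if (length(mats) == 0) stop("no encodable training pairs")
      graph_prep(mats, model$vocab, gc$max_len)
    } else {
      seq_prep(pairs, model$vocab, gc$max_len)
    }
  }
  ptrain <- prep_pairs(train)
  pvalid <- prep_pairs(valid)
  ntr <- nrow(if (graph) ptrain$enc_w else ptrain$enc)
  nva <- nrow(if (graph) pvalid$enc_w else pvalid$enc)
  if (ntr == 0) stop("empty training set")
  opt <- adam_init(model$params)
  trace <- data.frame(epoch = integer(0), train_nll = numeric(0),
                      valid_nll = numeric(0))
  best <- Inf; best_epoch <- 0L; best_snap <- NULL
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(ntr)
      tl <- 0; nb <- 0
      for (start in seq(1, ntr, by = tc$batch_size)) {
        ix <- ord[start:min(start + tc$batch_size - 1L, ntr)]
        loss <- generator_loss(model, .subset_batch(ptrain, ix, graph))
        lv <- ad_val(loss)[1]
        if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch)
        ad_backward(loss)
        opt <- adam_step(opt, model$params, lr = tc$lr)
        tl <- tl + lv; nb <- nb + 1
      }
      vl <- ad_no_grad({
        tot <- 0; m <- 0
        for (start in seq(1, nva, by = tc$batch_size)) {
          ix <- start:min(start + tc$batch_size - 1L, nva)
          tot <- tot + ad_val(generator_loss(
            model, .subset_batch(pvalid, ix, graph)))[1]
          m <- m + 1
        }
        tot / m
      })
      trace <- rbind(trace, data.frame(epoch = epoch, train_nll = tl / nb,
                                       valid_nll = vl))
      if (vl < best - 1e-9) {
        best <- vl; best_epoch <- epoch
        best_snap <- generator_snapshot(model)
      }
      if (!quiet && (epoch %% 10 == 0 || epoch == 1))
        scafgen_log("epoch %d: train %.4f valid %.4f", epoch, tl / nb, vl)
      if (epoch - best_epoch >= tc$patience) break
    }
  })
  if (!is.null(best_snap)) generator_restore(model, best_snap)
  model$trace <- trace
  model$best_epoch <- best_epoch
  model
}

# ---------------------------------------------------------------------------
# Sampling

.softmax_sample <- function(logits, allowed, greedy = FALSE) {
  # logits: numeric vector; allowed: 1-based index set into logits
  if (length(allowed) == 1L) return(allowed)
  z <- logits[allowed]
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  if (greedy) allowed[which.max(p)]
  else allowed[sample.int(length(allowed), 1L, prob = p)]
}

.sample_seq <- function(model, scaffolds, k, greedy = FALSE) {
  vocab <- model$vocab; gc <- model$gc
  V <- length(vocab$tokens)
  enc_rows <- lapply(scaffolds, function(s)
    tryCatch(encode_smiles(s, vocab, gc$max_len), error = function(e) NULL))
  ok <- !vapply(enc_rows, is.null, TRUE)
  if (any(!ok))
    scafgen_log("sample: skipped %d unencodable scaffold(s)", sum(!ok))
  idx <- rep(which(ok), each = k)
  if (length(idx) == 0) return(data.frame(scaffold = character(0),
                                          smiles = character(0)))
  enc <- do.call(rbind, enc_rows[idx])
  used <- which(colSums(enc != 0) > 0)
  enc <- enc[, seq_len(max(used)), drop = FALSE]
  B <- nrow(enc)
  Tmax <- gc$max_len - 1L
  toks <- matrix(1L, B, 1L)                 # GO index = 1 (0-based)
  done <- rep(FALSE, B)
  eos <- unname(vocab$index[["EOS"]])
  banned <- c(1L, 2L)                       # blank "_" and GO, 1-based
  lstm_kind <- model$kind %in% c("lstm-base", "lstm-attn")
  fwd <- if (model$kind == "seq-transformer") .fwd_seq_transformer
         else .fwd_lstm
  ad_no_grad({
    for (t in seq_len(Tmax)) {
      rows <- (seq_len(B) - 1L) * t + t    # last position of each sample
      logits <- ad_val(fwd(model, enc, toks, rows = rows))
      nxt <- integer(B)
      for (b in seq_len(B)) {
        if (done[b]) { nxt[b] <- 0L; next }
        lg <- logits[b, ]
        allowed <- setdiff(seq_len(V), banned)
        ch <- .softmax_sample(lg, allowed, greedy) - 1L
        nxt[b] <- ch
        if (ch == eos) done[b] <- TRUE
      }
      toks <- cbind(toks, nxt)
      if (all(done)) break
    }
  })
  smiles <- vapply(seq_len(B), function(b)
    decode_smiles(toks[b, -1], vocab), "")
  out <- data.frame(scaffold = scaffolds[idx], smiles = smiles,
                    stringsAsFactors = FALSE)
  attr(out, "enc") <- enc
  attr(out, "tokens") <- toks
  out
}

.sample_graph <- function(model, scaffolds, k, greedy = FALSE) {
  vocab <- model$vocab; gc <- model$gc
  L <- gc$max_len
  V <- length(vocab$tokens)
  eos <- unname(vocab$index[["EOS"]])
  prefixes <- scaffold_prefixes(scaffolds, vocab)
  ok <- !vapply(prefixes, is.null, TRUE) &
    vapply(prefixes, function(p) if (is.null(p)) Inf else ncol(p), 0) <= L - 4L
  if (any(!ok))
    scafgen_log("sample: skipped %d unencodable scaffold(s)", sum(!ok))
  idx <- rep(which(ok), each = k)
  if (length(idx) == 0) return(data.frame(scaffold = character(0),
                                          smiles = character(0)))
  B <- length(idx)
  pref <- prefixes[idx]
  Fmax <- max(vapply(pref, ncol, 0L))
  enc_w <- t(vapply(pref, function(m) {
    v <- m["atom", ] * 4L + m["bond", ]
    c(v, rep(0L, Fmax - length(v)))
  }, integer(Fmax)))
  enc_p <- t(vapply(pref, function(m) {
    v <- m["curr", ] * L + m["conn", ]
    c(v, rep(0L, Fmax - length(v)))
  }, integer(Fmax)))
  enc_mask <- t(vapply(pref, function(m)
    c(rep(TRUE, ncol(m)), rep(FALSE, Fmax - ncol(m))), logical(Fmax)))
  states <- lapply(pref, graph_state_init, vocab = vocab, L = L)
  cols <- lapply(seq_len(B), function(b) list())
  masks <- lapply(seq_len(B), function(b) list())   # allowed sets per step
  done <- rep(FALSE, B)
  p <- model$params
  go_w <- unname(vocab$index[["GO"]]) * 4L
  ad_no_grad({
    Tcap <- L - min(vapply(pref, ncol, 0L))
    stepper <- .graph_decoder_stepper(model, enc_w, enc_p, enc_mask,
                                      Tcap + 1L)
    new_w <- rep(go_w, B); new_p <- rep(0L, B)
    for (t in seq_len(Tcap)) {
      h <- stepper(new_w, new_p)
      atom_lg <- ad_val(ad_add(ad_matmul(h, p$W_atom), p$b_atom))
      a_ch <- integer(B)
      am <- bm <- cm <- um <- vector("list", B)
      for (b in seq_len(B)) {
        if (done[b]) { a_ch[b] <- 0L; next }
        st <- states[[b]]
        room_grow <- st$ncols < L - 2L
        room_link <- st$ncols < L - 1L
        allowed0 <- if ((st$phase == "grow" && !room_grow) ||
                        (st$phase == "link" && !room_link)) eos
                    else valence_mask(st, vocab)$atom
        am[[b]] <- allowed0
        a_ch[b] <- .softmax_sample(atom_lg[b, ], allowed0 + 1L, greedy) - 1L
      }
      s1 <- gru_step(ad_rows(p$EA, a_ch + 1L), h, p, "gru")
      bond_lg <- ad_val(ad_add(ad_matmul(s1, p$W_bond), p$b_bond))
      b_ch <- integer(B)
      for (b in seq_len(B)) {
        if (done[b] || a_ch[b] == eos) { b_ch[b] <- 0L; next }
        allowed <- mask_bond_choices(states[[b]], a_ch[b], vocab)
        bm[[b]] <- allowed
        b_ch[b] <- if (length(allowed) == 0) 0L
                   else .softmax_sample(bond_lg[b, ], allowed + 1L, greedy) - 1L
      }
      s2 <- gru_step(ad_rows(p$EB, b_ch + 1L), s1, p, "gru")
      conn_lg <- ad_val(ad_add(ad_matmul(s2, p$W_conn), p$b_conn))
      c_ch <- integer(B)
      for (b in seq_len(B)) {
        if (done[b] || a_ch[b] == eos || (a_ch[b] != 0L && b_ch[b] == 0L)) {
          c_ch[b] <- 0L; next
        }
        allowed <- mask_conn_choices(states[[b]], a_ch[b], b_ch[b], vocab)
        cm[[b]] <- allowed
        c_ch[b] <- if (length(allowed) == 0) 0L
                   else .softmax_sample(conn_lg[b, ], allowed + 1L, greedy) - 1L
      }
      s3 <- gru_step(ad_rows(p$EP, c_ch + 1L), s2, p, "gru")
      curr_lg <- ad_val(ad_add(ad_matmul(s3, p$W_curr), p$b_curr))
      u_ch <- integer(B)
      new_done <- done
      for (b in seq_len(B)) {
        if (done[b]) next
        st <- states[[b]]
        if (a_ch[b] == eos) {
          u_ch[b] <- 0L
        } else if (a_ch[b] != 0L && b_ch[b] == 0L) {
          u_ch[b] <- length(st$tokens) + 1L   # first atom of the molecule
        } else {
          allowed <- mask_curr_choices(st, a_ch[b], b_ch[b], c_ch[b], vocab)
          um[[b]] <- allowed
          u_ch[b] <- if (length(allowed) == 0) 0L
                     else .softmax_sample(curr_lg[b, ], allowed + 1L,
                                          greedy) - 1L
        }
        col <- c(a_ch[b], b_ch[b], c_ch[b], u_ch[b], 0L)
        states[[b]] <- graph_state_step(st, col, vocab)
        cols[[b]][[length(cols[[b]]) + 1L]] <- col
        masks[[b]][[length(masks[[b]]) + 1L]] <-
          list(atom = am[[b]], bond = bm[[b]], conn = cm[[b]],
               curr = um[[b]])
        if (states[[b]]$phase == "done") new_done[b] <- TRUE
      }
      done <- new_done
      new_w <- a_ch * 4L + b_ch
      new_p <- u_ch * L + c_ch
      if (all(done)) break
    }
  })
  mats <- lapply(seq_len(B), function(b) {
    m <- empty_graph_matrix(L)
    pc <- pref[[b]]
    m[, seq_len(ncol(pc))] <- pc
    for (j in seq_along(cols[[b]]))
      m[, ncol(pc) + j] <- cols[[b]][[j]]
    m
  })
  smiles <- decode_graphs(mats, vocab)
  out <- data.frame(scaffold = scaffolds[idx], smiles = smiles,
                    stringsAsFactors = FALSE)
  attr(out, "matrices") <- mats
  attr(out, "masks") <- masks
  out
}

#' Sample molecules conditioned on scaffolds
#'
#' Presents each scaffold `k` times and samples stepwise from the decoder
#' distribution (multinomial, temperature 1).  The graph model applies the
#' valence mask at every decision, so each of its emissions decodes to a
#' valid molecule; sequence models emit raw token strings whose validity is
#' checked downstream.
#'
#' @param model A trained `scafgen_generator`.
#' @param scaffolds Character vector of '.'-joined fragment SMILES.
#' @param k Repeats per scaffold (default 20).
#' @param seed RNG seed; the same seed reproduces the output exactly.
#' @param greedy Use argmax decoding instead of sampling.
#' @return data.frame with columns `scaffold` and `smiles` (`NA` smiles are
#'   never produced by the graph kind; sequence kinds may emit strings that
#'   fail to parse).
#' @export
sample_molecules <- function(model, scaffolds, k = 20L, seed = 1L,
                             greedy = FALSE) {
  with_seed(seed, {
    if (is_graph_kind(model$kind)) .sample_graph(model, scaffolds, k, greedy)
    else .sample_seq(model, scaffolds, k, greedy)
  })
}
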