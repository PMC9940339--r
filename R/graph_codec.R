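# Five-row graph-matrix codec and the valence-mask state machine.
#
# A molecule with an annotated fragment subset is encoded as a 5 x L
# integer matrix with rows (atom type, bond type, connected atom index,
# current atom index, fragment index).  Columns fall into three sections:
#
#   [GO] [fragment columns, frag >= 1] [growing columns, frag = 0]
#   [EOS] [linking columns: single bonds only, frag = 0] [EOS] [padding]
#
# Bond orders are kekulized before encoding (aromatic bonds interfere with
# valence bookkeeping); aromaticity is re-perceived by sanitization when a
# matrix is decoded.  The first occurrence of an atom carries its atom type
# and bond to an already-placed atom ('*' bond if it opens a fragment);
# ring-closure columns between placed atoms carry an empty atom type.
#
# The same bookkeeping drives the valence mask used during generation:
# a partial matrix is a state from which only continuations that keep every
# atom's bond-order sum within its maximum valence are allowed, which is
# what guarantees that every sampled matrix decodes to a valid molecule.

# 38 atom-type tokens: the organic subset plus explicit charge states.
.graph_atom_tokens <- c(
  "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se",
  "C+", "C-", "N+", "N-", "O+", "O-", "S+", "S-", "P+", "P-",
  "B+", "B-", "Si+", "Si-", "Se+", "Se-",
  "F-", "Cl-", "Br-", "I-",
  "N++", "N--", "O++", "S++", "S--", "C--")

.graph_max_valence <- c(
  "C" = 4, "N" = 3, "O" = 2, "S" = 6, "P" = 5, "F" = 1, "Cl" = 1,
  "Br" = 1, "I" = 1, "B" = 3, "Si" = 4, "Se" = 2,
  "C+" = 3, "C-" = 3, "N+" = 4, "N-" = 2, "O+" = 3, "O-" = 1,
  "S+" = 3, "S-" = 1, "P+" = 4, "P-" = 2, "B+" = 2, "B-" = 4,
  "Si+" = 3, "Si-" = 3, "Se+" = 3, "Se-" = 1,
  "F-" = 0, "Cl-" = 0, "Br-" = 0, "I-" = 0,
  "N++" = 3, "N--" = 1, "O++" = 4, "S++" = 4, "S--" = 0, "C--" = 2)

#' Graph vocabulary
#'
#' Atom-type tokens (index 0 is the blank token `*`, followed by `GO` and
#' `EOS`, then 38 element/charge tokens) and the fixed set of exactly four
#' bond types: none, single, double, triple.
#'
#' @param atoms Optional custom character vector of atom tokens (element
#'   symbol plus '+'/'-' repeats); defaults to the built-in 38-entry list.
#' @return Object of class `graph_vocab`.
#' @export
graph_vocab <- function(atoms = .graph_atom_tokens) {
  tokens <- c("*", "GO", "EOS", atoms)
  idx <- seq_along(tokens) - 1L
  names(idx) <- tokens
  maxval <- .graph_max_valence[atoms]
  maxval[is.na(maxval)] <- 4
  names(maxval) <- atoms
  structure(list(tokens = tokens, index = idx,
                 bond_types = c("*", "-", "=", "#"),
                 max_valence = maxval),
            class = "graph_vocab")
}

#' @export
print.graph_vocab <- function(x, ...) {
  cat(sprintf("<graph_vocab: %d atom tokens, %d bond types>\n",
              length(x$tokens), length(x$bond_types)))
  invisible(x)
}

#' Combined word index for a (atom type, bond type) pair
#'
#' `W = T_atom * 4 + T_bond`, injective because there are exactly four bond
#' types.  This is the token index fed to the graph generator's word
#' embedding.
#'
#' @param t_atom Atom-type index (0-based, within the graph vocabulary).
#' @param t_bond Bond-type index in 0..3.
#' @param n_atom_types Vocabulary size (for range checking).
#' @return Integer word index.
#' @export
graph_word_index <- function(t_atom, t_bond, n_atom_types = Inf) {
  if (any(t_bond < 0 | t_bond >= 4)) stop("bond-type index out of range 0..3")
  if (any(t_atom < 0 | t_atom >= n_atom_types)) stop("atom-type index out of range")
  as.integer(t_atom) * 4L + as.integer(t_bond)
}

#' Combined position index for a (current atom, connected atom) pair
#'
#' `P = I_atom * L_max + I_connected`, injective over index pairs below
#' `L_max`; `P` is then passed through the sinusoidal positional encoding.
#'
#' @param i_atom Current atom index (0-based).
#' @param i_connected Connected atom index (0-based).
#' @param L_max Maximum matrix width.
#' @return Integer position index.
#' @export
graph_position_index <- function(i_atom, i_connected, L_max) {
  if (any(i_atom < 0 | i_atom >= L_max) ||
      any(i_connected < 0 | i_connected >= L_max))
    stop("atom index out of range for L_max = ", L_max)
  as.integer(i_atom) * as.integer(L_max) + as.integer(i_connected)
}

.gm_rows <- c("atom", "bond", "conn", "curr", "frag")

empty_graph_matrix <- function(L) {
  m <- matrix(0L, 5L, L)
  rownames(m) <- .gm_rows
  m
}

# ---------------------------------------------------------------------------
# Encoding

# deterministic traversal of one fragment's atoms (0-based mol indices):
# breadth-first from the lowest canonical rank, neighbors by canonical rank
.traverse_component <- function(members, adj, ranks) {
  members <- members[order(ranks[members + 1L])]
  start <- members[1]
  seen <- c(start)
  queue <- list(start)
  order_out <- list(c(start, NA_integer_))  # atom, parent
  memset <- members
  while (length(queue)) {
    a <- queue[[1]]; queue <- queue[-1]
    nb <- adj[[a + 1L]]
    nb <- nb[nb %in% memset & !(nb %in% seen)]
    nb <- nb[order(ranks[nb + 1L])]
    for (b in nb) {
      seen <- c(seen, b)
      queue <- c(queue, b)
      order_out[[length(order_out) + 1L]] <- c(b, a)
    }
  }
  order_out
}

#' Encode molecules with fragment annotations as graph matrices
#'
#' Batch encoder: for each (molecule, fragment subset) item the molecule is
#' kekulized, the fragments are placed on disjoint atom sets, and the
#' five-row matrix is assembled (fragment sections first, then growing
#' columns, an EOS separator, linking single bonds, and a terminal EOS).
#'
#' @param items List of lists with elements `molecule` (SMILES) and
#'   `frags` (character vector of fragment SMILES).
#' @param vocab A [graph_vocab()].
#' @param L Matrix width (default 80).
#' @return List per item: either the 5 x L integer matrix or `NULL` with a
#'   logged reason (unkekulizable, unplaceable fragments, over-length).
#' @export
encode_graphs <- function(items, vocab = graph_vocab(), L = 80L) {
  mols <- vapply(items, function(x) x$molecule, "")
  umols <- unique(mols)
  ginfo <- chem_call("mol_graph", smiles = as.list(umols))$graphs
  names(ginfo) <- umols
  maps <- chem_call("frag_map", items = lapply(items, function(x)
    list(mol = x$molecule, frags = as.list(x$frags))))$maps
  out <- vector("list", length(items))
  nbad <- 0
  for (i in seq_along(items)) {
    g <- ginfo[[mols[i]]]
    fm <- maps[[i]]
    if (!isTRUE(g$ok) || is.null(fm)) { nbad <- nbad + 1; next }
    enc <- tryCatch(
      .encode_one_graph(g, lapply(fm, function(m) as.integer(unlist(m))),
                        vocab, L),
      error = function(e) NULL)
    if (is.null(enc)) { nbad <- nbad + 1; next }
    out[[i]] <- enc
  }
  if (nbad > 0)
    scafgen_log("encode_graphs: %d item(s) could not be encoded", nbad)
  out
}

.encode_one_graph <- function(g, frag_atoms, vocab, L) {
  atoms <- vapply(g$atoms, identity, "")
  bonds <- g$bonds  # list of [i, j, order], 0-based
  ranks <- as.integer(unlist(g$ranks))
  natom <- length(atoms)
  if (any(!atoms %in% vocab$tokens))
    stop("atom token outside vocabulary: ",
         paste(setdiff(atoms, vocab$tokens), collapse = " "))
  adj <- rep(list(integer(0)), natom)
  border <- matrix(0L, natom, natom)
  for (b in bonds) {
    i <- b[[1]]; j <- b[[2]]; o <- b[[3]]
    adj[[i + 1L]] <- c(adj[[i + 1L]], j)
    adj[[j + 1L]] <- c(adj[[j + 1L]], i)
    border[i + 1L, j + 1L] <- border[j + 1L, i + 1L] <- as.integer(o)
  }

  num <- rep(NA_integer_, natom)   # mol atom -> matrix atom number (1-based)
  nextnum <- 1L
  emitted <- matrix(FALSE, natom, natom)
  cols <- list(c(vocab$index[["GO"]], 0L, 0L, 0L, 0L))
  comp <- seq_len(natom)           # union-find over mol atoms (1-based)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  union_ <- function(x, y) comp[find(x)] <<- find(y)

  emit <- function(a_tok, b_ord, conn, curr, frag)
    cols[[length(cols) + 1L]] <<- c(a_tok, b_ord, conn, curr, frag)

  place_bond <- function(i, j) {       # 0-based mol atoms, both placed
    emitted[i + 1L, j + 1L] <<- emitted[j + 1L, i + 1L] <<- TRUE
    union_(i + 1L, j + 1L)
  }

  # fragment sections
  for (k in seq_along(frag_atoms)) {
    members <- frag_atoms[[k]]
    # fragments may themselves be disconnected inside the molecule only if
    # matched across components; traverse each connected piece
    rest <- members
    while (length(rest)) {
      trav <- .traverse_component(rest, lapply(adj, function(x)
        x[x %in% rest]), ranks)
      for (step in trav) {
        a <- step[1]; parent <- step[2]
        num[a + 1L] <- nextnum
        if (is.na(parent)) {
          emit(vocab$index[[atoms[a + 1L]]], 0L, 0L, nextnum, k)
        } else {
          emit(vocab$index[[atoms[a + 1L]]], border[a + 1L, parent + 1L],
               num[parent + 1L], nextnum, k)
          place_bond(a, parent)
        }
        nextnum <- nextnum + 1L
        # intra-fragment ring closures from this atom to placed members
        part <- adj[[a + 1L]]
        part <- part[part %in% members & !is.na(num[part + 1L])]
        part <- part[order(num[part + 1L])]
        for (p in part) {
          if (!emitted[a + 1L, p + 1L]) {
            emit(0L, border[a + 1L, p + 1L], num[p + 1L], num[a + 1L], k)
            place_bond(a, p)
          }
        }
      }
      rest <- setdiff(rest, trav |> vapply(`[`, 0L, 1L))
    }
  }

  # growing section: BFS outward from placed atoms over the whole molecule
  linking <- list()
  queue <- order(num)[seq_len(nextnum - 1L)] - 1L  # 0-based, by number
  handle_closures <- function(a) {
    part <- adj[[a + 1L]]
    part <- part[!is.na(num[part + 1L])]
    part <- part[order(num[part + 1L])]
    for (p in part) {
      if (emitted[a + 1L, p + 1L]) next
      o <- border[a + 1L, p + 1L]
      if (o == 1L && find(a + 1L) != find(p + 1L)) {
        # defer single bonds that join distinct components to the linker
        linking[[length(linking) + 1L]] <<-
          c(0L, 1L, min(num[p + 1L], num[a + 1L]),
            max(num[p + 1L], num[a + 1L]), 0L)
        place_bond(a, p)
      } else {
        emit(0L, o, num[p + 1L], num[a + 1L], 0L)
        place_bond(a, p)
      }
    }
  }
  for (a in queue) handle_closures(a)
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    nb <- adj[[a + 1L]]
    nb <- nb[is.na(num[nb + 1L])]
    nb <- nb[order(ranks[nb + 1L])]
    for (b in nb) {
      if (!is.na(num[b + 1L])) next
      num[b + 1L] <- nextnum
      emit(vocab$index[[atoms[b + 1L]]], border[b + 1L, a + 1L],
           num[a + 1L], nextnum, 0L)
      place_bond(b, a)
      nextnum <- nextnum + 1L
      handle_closures(b)
      queue <- c(queue, b)
    }
  }
  if (any(is.na(num))) stop("disconnected atoms not reachable from fragments")

  emit(vocab$index[["EOS"]], 0L, 0L, 0L, 0L)
  for (lc in linking) cols[[length(cols) + 1L]] <- lc
  emit(vocab$index[["EOS"]], 0L, 0L, 0L, 0L)

  if (length(cols) > L)
    stop(sprintf("matrix needs %d columns but L = %d", length(cols), L))
  m <- empty_graph_matrix(L)
  for (ci in seq_along(cols)) m[, ci] <- cols[[ci]]
  m
}

#' Encode a single molecule
#' @param molecule Molecule SMILES.
#' @param frags Character vector of fragment SMILES to annotate.
#' @inheritParams encode_graphs
#' @return 5 x L integer matrix.
#' @export
encode_graph <- function(molecule, frags, vocab = graph_vocab(), L = 80L) {
  res <- encode_graphs(list(list(molecule = molecule, frags = frags)),
                       vocab, L)[[1]]
  if (is.null(res)) stop("could not encode molecule: ", molecule)
  res
}

# ---------------------------------------------------------------------------
# Decoding

# pure-R pass: matrix -> atom tokens + bond list (molecule assembly and
# sanitization are delegated to the chemistry backend)
.graph_matrix_parts <- function(m, vocab) {
  eos <- vocab$index[["EOS"]]; go <- vocab$index[["GO"]]
  atoms <- character(0)   # token per atom number
  bonds <- list()
  n_eos <- 0L
  for (ci in seq_len(ncol(m))) {
    a <- m["atom", ci]; b <- m["bond", ci]
    conn <- m["conn", ci]; curr <- m["curr", ci]
    if (a == go) next
    if (a == eos) {
      n_eos <- n_eos + 1L
      if (n_eos >= 2L) break
      next
    }
    if (a == 0L && b == 0L) {
      if (n_eos >= 1L) break  # padding after separator with empty linker
      next
    }
    if (a != 0L) {
      tok <- vocab$tokens[a + 1L]
      if (curr != length(atoms) + 1L)
        stop(sprintf("column %d: new atom numbered %d, expected %d",
                     ci, curr, length(atoms) + 1L))
      atoms <- c(atoms, tok)
    }
    if (b != 0L) {
      if (conn < 1L || conn > length(atoms) || curr < 1L || curr > length(atoms))
        stop(sprintf("column %d: bond references unknown atom", ci))
      bonds[[length(bonds) + 1L]] <- c(conn - 1L, curr - 1L, b)
    }
  }
  if (length(atoms) == 0) stop("matrix decodes to an empty molecule")
  list(atoms = atoms, bonds = bonds)
}

#' Decode graph matrices to molecules
#'
#' Walks the matrix column by column, instantiates atoms and kekulized
#' bonds, and sanitizes the assembled molecule (aromaticity is re-perceived
#' automatically).
#'
#' @param mats List of 5 x L integer matrices.
#' @param vocab A [graph_vocab()].
#' @return Character vector of canonical SMILES (`NA` where decoding or
#'   sanitization failed).
#' @export
decode_graphs <- function(mats, vocab = graph_vocab(), details = FALSE) {
  parts <- lapply(mats, function(m) {
    tryCatch(.graph_matrix_parts(m, vocab),
             error = function(e) structure(list(), reason = conditionMessage(e)))
  })
  ok <- vapply(parts, function(p) length(p) > 0, TRUE)
  out <- rep(NA_character_, length(mats))
  reason <- vapply(parts, function(p)
    if (length(p) == 0) attr(p, "reason") else NA_character_, "")
  if (any(ok)) {
    res <- chem_call("mol_from_graph",
                     graphs = lapply(parts[ok], function(p)
                       list(atoms = as.list(p$atoms), bonds = p$bonds)))
    out[ok] <- vapply(res$molecules, function(mol)
      if (isTRUE(mol$ok)) mol$smiles else NA_character_, "")
    reason[ok] <- vapply(res$molecules, function(mol)
      if (isTRUE(mol$ok)) NA_character_ else mol$reason, "")
  }
  if (details) data.frame(smiles = out, reason = reason,
                          stringsAsFactors = FALSE)
  else out
}

#' @rdname decode_graphs
#' @param m A single graph matrix.
#' @export
decode_graph <- function(m, vocab = graph_vocab()) {
  decode_graphs(list(m), vocab)[[1]]
}

# ---------------------------------------------------------------------------
# Scaffold prefixes (fragment sections without a target molecule)

# columns of a single fragment traversed as its own small graph
.fragment_cols <- function(g, k, offset, vocab) {
  atoms <- vapply(g$atoms, identity, "")
  natom <- length(atoms)
  adj <- rep(list(integer(0)), natom)
  border <- matrix(0L, natom, natom)
  for (b in g$bonds) {
    i <- b[[1]]; j <- b[[2]]; o <- b[[3]]
    adj[[i + 1L]] <- c(adj[[i + 1L]], j)
    adj[[j + 1L]] <- c(adj[[j + 1L]], i)
    border[i + 1L, j + 1L] <- border[j + 1L, i + 1L] <- as.integer(o)
  }
  ranks <- as.integer(unlist(g$ranks))
  num <- rep(NA_integer_, natom)
  nextnum <- offset
  emitted <- matrix(FALSE, natom, natom)
  cols <- list()
  trav <- .traverse_component(seq_len(natom) - 1L, adj, ranks)
  for (step in trav) {
    a <- step[1]; parent <- step[2]
    num[a + 1L] <- nextnum
    if (is.na(parent)) {
      cols[[length(cols) + 1L]] <-
        c(vocab$index[[atoms[a + 1L]]], 0L, 0L, nextnum, k)
    } else {
      cols[[length(cols) + 1L]] <-
        c(vocab$index[[atoms[a + 1L]]], border[a + 1L, parent + 1L],
          num[parent + 1L], nextnum, k)
      emitted[a + 1L, parent + 1L] <- emitted[parent + 1L, a + 1L] <- TRUE
    }
    nextnum <- nextnum + 1L
    part <- adj[[a + 1L]]
    part <- part[!is.na(num[part + 1L])]
    part <- part[order(num[part + 1L])]
    for (p in part) {
      if (!emitted[a + 1L, p + 1L]) {
        cols[[length(cols) + 1L]] <-
          c(0L, border[a + 1L, p + 1L], num[p + 1L], num[a + 1L], k)
        emitted[a + 1L, p + 1L] <- emitted[p + 1L, a + 1L] <- TRUE
      }
    }
  }
  list(cols = cols, natoms = natom)
}

#' Build fragment-section prefixes for scaffolds
#'
#' Encodes each '.'-joined scaffold as the GO column plus the fragment
#' columns of the five-row matrix -- the part of the matrix that is given
#' (not generated) during scaffold-conditioned sampling.
#'
#' @param scaffolds Character vector of '.'-joined fragment SMILES.
#' @param vocab A [graph_vocab()].
#' @return List per scaffold: a 5 x k integer matrix, or `NULL` if a
#'   fragment could not be kekulized/encoded.
#' @export
scaffold_prefixes <- function(scaffolds, vocab = graph_vocab()) {
  fraglists <- strsplit(scaffolds, ".", fixed = TRUE)
  ufrags <- unique(unlist(fraglists))
  ginfo <- chem_call("mol_graph", smiles = as.list(ufrags))$graphs
  names(ginfo) <- ufrags
  lapply(fraglists, function(frs) {
    cols <- list(c(vocab$index[["GO"]], 0L, 0L, 0L, 0L))
    offset <- 1L
    for (k in seq_along(frs)) {
      g <- ginfo[[frs[k]]]
      if (!isTRUE(g$ok)) return(NULL)
      fc <- tryCatch(.fragment_cols(g, k, offset, vocab),
                     error = function(e) NULL)
      if (is.null(fc)) return(NULL)
      cols <- c(cols, fc$cols)
      offset <- offset + fc$natoms
    }
    m <- matrix(unlist(cols), nrow = 5L)
    rownames(m) <- .gm_rows
    m
  })
}

# ---------------------------------------------------------------------------
# Valence-mask state machine

#' Initialize a generation state from a fragment section
#'
#' Replays the fragment (and any other prefix) columns of a matrix into the
#' bookkeeping used by the valence mask: per-atom remaining valence,
#' connected components, and section phase.
#'
#' @param prefix 5 x k integer matrix (columns so far), or `NULL` for an
#'   empty state.
#' @param vocab A [graph_vocab()].
#' @param L Matrix width bound.
#' @return A `graph_state` list.
#' @export
graph_state_init <- function(prefix = NULL, vocab = graph_vocab(), L = 80L) {
  st <- list(tokens = character(0), rem = numeric(0), comp = integer(0),
             bonded = list(), phase = "grow", ncols = 0L, L = L,
             vocab_hash = length(vocab$tokens))
  class(st) <- "graph_state"
  if (!is.null(prefix)) {
    for (ci in seq_len(ncol(prefix))) st <- graph_state_step(st, prefix[, ci], vocab)
  }
  st
}

uf_find <- function(comp, x) { while (comp[x] != x) x <- comp[x]; x }

#' Advance a generation state by one column
#'
#' @param st A `graph_state`.
#' @param col Integer vector of length 5 (atom, bond, conn, curr, frag).
#' @param vocab A [graph_vocab()].
#' @return Updated state; `st$phase` becomes `"link"` after the first EOS
#'   and `"done"` after the second.
#' @export
graph_state_step <- function(st, col, vocab = graph_vocab()) {
  a <- col[1]; b <- col[2]; conn <- col[3]; curr <- col[4]
  go <- vocab$index[["GO"]]; eos <- vocab$index[["EOS"]]
  st$ncols <- st$ncols + 1L
  if (a == go) return(st)
  if (a == eos) {
    st$phase <- if (st$phase == "grow") "link" else "done"
    return(st)
  }
  if (a == 0L && b == 0L) return(st)  # blank
  if (a != 0L) {
    tok <- vocab$tokens[a + 1L]
    st$tokens <- c(st$tokens, tok)
    st$rem <- c(st$rem, unname(vocab$max_valence[tok]))
    st$comp <- c(st$comp, length(st$comp) + 1L)
    st$bonded[[length(st$tokens)]] <- integer(0)
  }
  if (b != 0L) {
    st$rem[conn] <- st$rem[conn] - b
    st$rem[curr] <- st$rem[curr] - b
    st$comp[uf_find(st$comp, conn)] <- uf_find(st$comp, curr)
    st$bonded[[conn]] <- c(st$bonded[[conn]], curr)
    st$bonded[[curr]] <- c(st$bonded[[curr]], conn)
  }
  st
}

# candidate ring-closure pairs: distinct placed atoms, both with free
# valence, not already bonded to each other
.closure_possible <- function(st) {
  idx <- which(st$rem >= 1)
  if (length(idx) < 2) return(FALSE)
  for (i in idx) {
    others <- setdiff(idx, c(i, st$bonded[[i]]))
    if (length(others)) return(TRUE)
  }
  FALSE
}

.link_pairs_exist <- function(st) {
  idx <- which(st$rem >= 1)
  if (length(idx) < 2) return(FALSE)
  roots <- vapply(idx, function(i) uf_find(st$comp, i), 0L)
  length(unique(roots)) > 1
}

#' Allowed continuations under the valence rule
#'
#' Computes, for the current state, the sets of admissible atom types, bond
#' orders and positions.  The end token is always admissible, so the
#' returned sets are never empty; everything else is admitted exactly when
#' some completion keeps every atom's bond-order sum within its maximum
#' valence and the matrix structurally well-formed.
#'
#' @param st A `graph_state`.
#' @param vocab A [graph_vocab()].
#' @return List with 0-based index vectors `atom` (atom-type tokens, may
#'   include 0 = `*` for ring closure and the EOS index), `bond` (orders
#'   1..3 admissible for a new-atom attachment), `conn` (1-based positions
#'   with free valence) and `curr` (candidate current positions: the next
#'   free atom number for a new atom, plus closure candidates).
#' @export
valence_mask <- function(st, vocab = graph_vocab()) {
  eos <- vocab$index[["EOS"]]
  n <- length(st$tokens)
  if (st$phase == "done")
    return(list(atom = eos, bond = integer(0), conn = integer(0),
                curr = integer(0)))
  free <- which(st$rem >= 1)
  if (st$phase == "link") {
    if (.link_pairs_exist(st))
      return(list(atom = c(0L, eos), bond = 1L, conn = free,
                  curr = free))
    return(list(atom = eos, bond = integer(0), conn = integer(0),
                curr = integer(0)))
  }
  # growing phase
  atom_ok <- integer(0)
  bond_ok <- integer(0)
  conn_ok <- integer(0)
  curr_ok <- integer(0)
  room <- n + 1L <= st$L - 4L  # leave room for EOS separator/terminator
  if (n == 0L) {
    # empty state: any atom with positive valence opens the molecule
    real <- vocab$tokens[-(1:3)]
    atom_ok <- unname(vocab$index[real[vocab$max_valence[real] >= 1]])
    curr_ok <- 1L
  } else if (room && length(free) > 0) {
    maxrem <- max(st$rem[free])
    orders <- seq_len(min(3, maxrem))
    real <- vocab$tokens[-(1:3)]
    ok <- vocab$max_valence[real] >= 1  # new atom must afford one bond
    atom_ok <- unname(vocab$index[real[ok]])
    bond_ok <- orders
    conn_ok <- free
    curr_ok <- n + 1L
  }
  if (n > 0L && .closure_possible(st)) {
    atom_ok <- c(0L, atom_ok)
    bond_ok <- sort(unique(c(bond_ok, 1L)))
    conn_ok <- sort(unique(c(conn_ok, which(st$rem >= 1))))
    curr_ok <- sort(unique(c(curr_ok, which(st$rem >= 1))))
  }
  list(atom = c(atom_ok, eos), bond = bond_ok, conn = conn_ok,
       curr = curr_ok)
}

# ---------------------------------------------------------------------------
# Per-decision masks (conditional refinements of valence_mask, used while
# sampling the four decisions of a column one by one)

# allowed bond orders after the atom-type decision
mask_bond_choices <- function(st, atom_idx, vocab = graph_vocab()) {
  eos <- vocab$index[["EOS"]]
  if (atom_idx == eos) return(integer(0))
  if (atom_idx == 0L) {                       # ring closure / link bond
    if (st$phase == "link") return(1L)
    idx <- which(st$rem >= 1)
    best <- 0L
    for (i in idx) {
      others <- setdiff(idx, c(i, st$bonded[[i]]))
      if (length(others))
        best <- max(best, min(max(st$rem[others]), st$rem[i]))
    }
    if (best == 0L) return(integer(0))
    return(seq_len(min(3L, best)))
  }
  tok <- vocab$tokens[atom_idx + 1L]
  cap <- min(3, vocab$max_valence[[tok]], max(c(0, st$rem)))
  if (length(st$tokens) == 0L) return(0L)     # first atom: no bond yet
  if (cap < 1) return(integer(0))
  seq_len(cap)
}

# allowed connected-atom positions after (atom, bond)
mask_conn_choices <- function(st, atom_idx, bond, vocab = graph_vocab()) {
  eos <- vocab$index[["EOS"]]
  if (atom_idx == eos) return(integer(0))
  if (atom_idx != 0L && bond == 0L) return(0L)  # first atom of the molecule
  cand <- which(st$rem >= bond)
  if (atom_idx == 0L) {
    # closure: keep atoms that still have a valid partner
    keep <- vapply(cand, function(i) {
      others <- setdiff(cand, c(i, st$bonded[[i]]))
      if (st$phase == "link") {
        ri <- uf_find(st$comp, i)
        others <- others[vapply(others, function(j)
          uf_find(st$comp, j) != ri, TRUE)]
      }
      length(others) > 0
    }, TRUE)
    cand <- cand[keep]
  }
  cand
}

# allowed current-atom positions after (atom, bond, conn)
mask_curr_choices <- function(st, atom_idx, bond, conn,
                              vocab = graph_vocab()) {
  eos <- vocab$index[["EOS"]]
  if (atom_idx == eos) return(integer(0))
  if (atom_idx != 0L) return(length(st$tokens) + 1L)  # new atom: next index
  cand <- which(st$rem >= bond)
  cand <- setdiff(cand, c(conn, st$bonded[[conn]]))
  if (st$phase == "link") {
    rc <- uf_find(st$comp, conn)
    cand <- cand[vapply(cand, function(j) uf_find(st$comp, j) != rc, TRUE)]
  }
  cand
}

#' Sample graph matrices under a uniform random policy
#'
#' Draws every decision (atom type, bond type, connected and current
#' position) uniformly from the sets permitted by the valence mask,
#' starting from the given scaffold prefixes.  This is the adversarial
#' stress test of the masking machinery: any matrix it emits must decode
#' to a valid molecule, whatever the policy.
#'
#' @param n Number of matrices.
#' @param prefixes List of prefix matrices (from [scaffold_prefixes()]),
#'   recycled over `n`.
#' @param vocab A [graph_vocab()].
#' @param L Matrix width.
#' @param seed RNG seed.
#' @param p_stop Probability of choosing EOS whenever it is allowed
#'   alongside other choices (keeps molecule sizes reasonable).
#' @return List of `n` complete 5 x L matrices.
#' @export
sample_masked_random <- function(n, prefixes, vocab = graph_vocab(),
                                 L = 60L, seed = 1L, p_stop = 0.15) {
  eos <- unname(vocab$index[["EOS"]])
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pref <- prefixes[[((i - 1L) %% length(prefixes)) + 1L]]
      st <- graph_state_init(pref, vocab, L)
      cols <- list()
      while (st$phase != "done") {
        room <- if (st$phase == "grow") st$ncols < L - 2L
                else st$ncols < L - 1L
        allowed <- if (!room) eos else valence_mask(st, vocab)$atom
        a <- if (length(allowed) > 1 && eos %in% allowed &&
                 stats::runif(1) < p_stop) eos
             else sample(rep(allowed, 2), 1)     # rep() guards length-1
        if (a == eos) {
          col <- c(eos, 0L, 0L, 0L, 0L)
        } else {
          bonds <- mask_bond_choices(st, a, vocab)
          b <- if (length(bonds) == 0) 0L else sample(rep(bonds, 2), 1)
          conn <- mask_conn_choices(st, a, b, vocab)
          cn <- if (length(conn) == 0) 0L else sample(rep(conn, 2), 1)
          cu <- if (a != 0L && b == 0L) length(st$tokens) + 1L
                else {
                  curr <- mask_curr_choices(st, a, b, cn, vocab)
                  if (length(curr) == 0) 0L else sample(rep(curr, 2), 1)
                }
          col <- c(a, b, cn, cu, 0L)
        }
        st <- graph_state_step(st, col, vocab)
        cols[[length(cols) + 1L]] <- col
      }
      m <- empty_graph_matrix(L)
      m[, seq_len(ncol(pref))] <- pref
      for (j in seq_along(cols)) m[, ncol(pref) + j] <- cols[[j]]
      m
    })
  })
}
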