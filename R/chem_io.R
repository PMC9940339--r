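# Molecule table I/O, standardization, and the synthetic fixture library.
#
# A molecule table is a plain data.frame with columns `smiles` (canonical
# SMILES), `id` (opaque string) and `pX` (optional pChEMBL-scale activity,
# -log10 molar).  Tables are serialized as tab-separated text with a header.

#' Run code with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that library fixtures
#' and splits do not perturb the global RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Standardize molecules
#'
#' Keeps the largest organic component of each structure, neutralizes
#' charges where chemically possible, and canonicalizes the SMILES.
#' Structures whose largest component contains a metal (any element outside
#' the organic subset B, C, N, O, F, Si, P, S, Cl, Se, Br, I) are rejected,
#' as are unparsable inputs.  Molecules whose charge cannot be neutralized
#' (e.g. quaternary nitrogen) are kept in their charged form and flagged.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with columns `input`, `ok` (logical), `smiles`
#'   (canonical standardized SMILES or `NA`), `charged` (logical: residual
#'   formal charge kept), `reason` (rejection reason or `NA`).
#' @export
#' @examples \dontrun{
#' standardize_molecules(c("CC(=O)[O-].[Na+]", "CCO"))
#' }
standardize_molecules <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(input = as.character(smiles), ok = logical(n),
                    smiles = NA_character_, charged = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  res <- chem_call("standardize", smiles = as.list(as.character(smiles)))
  for (i in seq_len(n)) {
    r <- res$records[[i]]
    if (isTRUE(r$ok)) {
      out$ok[i] <- TRUE
      out$smiles[i] <- r$smiles
      out$charged[i] <- isTRUE(r$charged)
    } else {
      out$reason[i] <- r$reason
    }
  }
  ncharged <- sum(out$charged)
  if (ncharged > 0)
    scafgen_log("standardize: %d molecule(s) kept with residual formal charge",
                ncharged)
  out
}

#' Read a molecule table
#'
#' Reads a delimited text file (tab-separated by default) with a header row,
#' standardizes every structure, skips unparsable or rejected rows (with a
#' logged count) and collapses duplicate structures, averaging their
#' activity values.
#'
#' @param path File path.
#' @param smiles_col Name of the SMILES column.
#' @param id_col Optional name of an identifier column.
#' @param activity_col Optional name of the activity (pX) column.
#' @param sep Field separator.
#' @param standardize Standardize structures (default `TRUE`).
#' @return A molecule table: data.frame with columns `smiles`, `id`, `pX`.
#' @export
read_smiles_table <- function(path, smiles_col = "smiles", id_col = NULL,
                              activity_col = NULL, sep = "\t",
                              standardize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  for (col in c(smiles_col, id_col, activity_col)) {
    if (!is.null(col) && !col %in% names(raw))
      stop(sprintf("column '%s' not present in %s", col, path))
  }
  if (nrow(raw) == 0) stop("no molecule rows in ", path)
  smi <- as.character(raw[[smiles_col]])
  ids <- if (!is.null(id_col)) as.character(raw[[id_col]])
         else sprintf("mol%04d", seq_along(smi))
  px <- if (!is.null(activity_col)) as.numeric(raw[[activity_col]])
        else rep(NA_real_, length(smi))
  if (standardize) {
    std <- standardize_molecules(smi)
    keep <- std$ok
    if (any(!keep))
      scafgen_log("read_smiles_table: skipped %d unusable row(s)", sum(!keep))
    smi <- std$smiles[keep]
  } else {
    can <- canonical_smiles(smi)
    keep <- !is.na(can)
    if (any(!keep))
      scafgen_log("read_smiles_table: skipped %d unparsable row(s)", sum(!keep))
    smi <- can[keep]
  }
  ids <- ids[keep]; px <- px[keep]
  if (length(smi) == 0) stop("no parsable molecules in ", path)
  # collapse duplicate structures, average their activities
  agg <- split(seq_along(smi), smi)
  first <- vapply(agg, `[`, 1L, 1L)
  ord <- order(first)
  agg <- agg[ord]
  tbl <- data.frame(
    smiles = names(agg),
    id = vapply(agg, function(ix) ids[ix[1]], ""),
    pX = vapply(agg, function(ix) {
      v <- px[ix]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  tbl
}

#' Write a molecule table
#'
#' @param tbl Molecule table (`smiles`, optionally `id`, `pX`, more).
#' @param path Output path; tab-separated with header.
#' @export
write_smiles_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Synthetic fixture library

# Decoration templates for five ring families common among adenosine-receptor
# antagonist chemotypes.  `{A}`/`{B}` are substitution slots; empty
# substituents remove the enclosing branch.
.fixture_cores <- data.frame(
  family = c("furan", "triazine", "aminotriazole", "xanthine", "azapurine"),
  template = c(
    "{A}c1ccc({B})o1",
    "Nc1nc({A})nc({B})n1",
    "Nc1nc({A})nn1{B}",
    "O=c1[nH]c(=O)c2c(n1{A})nc({B})[nH]2",
    "Nc1nc2c({A})cnn2c({B})n1"),
  # planted activity signal: family base value on the pChEMBL scale
  base_px = c(4.8, 5.6, 6.9, 7.8, 8.3),
  stringsAsFactors = FALSE)

# ring label 9 avoids collisions with the ring digits used in templates
.fixture_subs <- c("", "C", "CC", "CCC", "C(C)C", "N", "NC", "O", "OC",
                   "OCC", "F", "Cl", "C#N", "C(=O)N", "c9ccccc9")

.fixture_fill <- function(template, a, b) {
  s <- template
  for (slot in c("A", "B")) {
    sub <- if (slot == "A") a else b
    br <- paste0("({", slot, "})")
    if (nzchar(sub)) {
      s <- sub(br, paste0("(", sub, ")"), s, fixed = TRUE)
      s <- sub(paste0("{", slot, "}"), sub, s, fixed = TRUE)
    } else {
      s <- sub(br, "", s, fixed = TRUE)
      s <- sub(paste0("{", slot, "}"), "", s, fixed = TRUE)
    }
  }
  s
}

# Enumerate, standardize and deduplicate the full decoration space once per
# session; the result is deterministic (no RNG involved).
fixture_space <- function() {
  if (!is.null(.scafgen$fixture_space)) return(.scafgen$fixture_space)
  cores <- .fixture_cores
  grid <- expand.grid(core = seq_len(nrow(cores)),
                      a = .fixture_subs, b = .fixture_subs,
                      stringsAsFactors = FALSE)
  raw <- mapply(function(ci, a, b) .fixture_fill(cores$template[ci], a, b),
                grid$core, grid$a, grid$b)
  std <- standardize_molecules(raw)
  ok <- std$ok
  smi <- std$smiles[ok]
  fam <- cores$family[grid$core[ok]]
  base <- cores$base_px[grid$core[ok]]
  nsub <- nchar(gsub("[^A-Za-z]", "", paste0(grid$a[ok], grid$b[ok])))
  dup <- duplicated(smi)
  space <- data.frame(smiles = smi[!dup], family = fam[!dup],
                      base_px = base[!dup], nsub = nsub[!dup],
                      stringsAsFactors = FALSE)
  .scafgen$fixture_space <- space
  space
}

#' Generate a synthetic molecule library
#'
#' Builds `n` distinct, valid, standardized molecules by combinatorially
#' decorating a fixed panel of heteroaromatic cores (furan, triazine,
#' aminotriazole, xanthine-like and azapurine-like families) with small
#' substituents.  Each molecule carries a deterministic pseudo-activity:
#' a family-specific base value on the pChEMBL scale, a small contribution
#' from decoration size, and Gaussian noise (sd 0.3) drawn from `seed`.
#' The planted family signal makes the library usable end-to-end: an
#' activity regressor trained on it recovers signal, and reinforcement
#' learning can discover the high-activity families.
#'
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @param n Number of molecules (at most the size of the enumerable space).
#' @return Molecule table with columns `smiles`, `id`, `pX`, `family`.
#' @export
#' @examples \dontrun{lib <- generate_fixture_library(seed = 1, n = 200)}
generate_fixture_library <- function(seed, n) {
  stopifnot(n >= 1)
  space <- fixture_space()
  if (n > nrow(space))
    stop(sprintf("n = %d exceeds the enumerable fixture space (maximum %d)",
                 n, nrow(space)))
  with_seed(seed, {
    pick <- sample.int(nrow(space), n)
    lib <- space[pick, , drop = FALSE]
    px <- lib$base_px + 0.04 * pmin(lib$nsub, 10) + stats::rnorm(n, 0, 0.3)
    data.frame(smiles = lib$smiles,
               id = sprintf("fix%04d", seq_len(n)),
               pX = pmin(pmax(px, 3), 12),
               family = lib$family,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# logging -------------------------------------------------------------------

#' Package log messages
#'
#' Messages go to stderr via [message()]; an optional log file sink can be
#' set with `options(scafgen.logfile = path)`.
#' @keywords internal
scafgen_log <- function(fmt, ...) {
  txt <- sprintf(fmt, ...)
  message("[scafgen] ", txt)
  lf <- getOption("scafgen.logfile")
  if (!is.null(lf)) cat(format(Sys.time(), "%H:%M:%S "), txt, "\n",
                        file = lf, append = TRUE)
  invisible(txt)
}
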