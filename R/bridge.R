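# Batched subprocess bridge to the RDKit backend.
#
# Every chemistry primitive (parsing, canonicalization, BRICS decomposition,
# fingerprints, QED/SA, substructure matching, molecule assembly) runs in a
# single short-lived python process per *batch*, exchanging JSON files.
# Callers must therefore batch aggressively; all exported wrappers below are
# vectorized over molecules.

.scafgen <- new.env(parent = emptyenv())

chem_script <- function() {
  p <- system.file("python", "chemtools.py", package = "scafgen")
  if (!nzchar(p)) {
    # during development (pkgload) inst/ is mapped directly
    p <- file.path("inst", "python", "chemtools.py")
  }
  if (!file.exists(p)) stop("chemtools.py backend script not found")
  p
}

python_bin <- function() {
  if (!is.null(.scafgen$python)) return(.scafgen$python)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter with RDKit found on PATH")
  .scafgen$python <- unname(p)
  .scafgen$python
}

# start (or restart) the persistent backend server; returns a socket
# connection or NULL when serving is unavailable in this environment
.chem_server_start <- function() {
  port_file <- tempfile(fileext = ".port")
  ok <- tryCatch({
    system2(python_bin(), c(chem_script(), "--serve", port_file),
            stdout = FALSE, stderr = FALSE, wait = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  for (i in 1:100) {                     # wait for the port announcement
    if (file.exists(port_file) && nzchar(readLines(port_file, warn = FALSE)[1]))
      break
    Sys.sleep(0.05)
  }
  if (!file.exists(port_file)) return(NULL)
  port <- suppressWarnings(as.integer(readLines(port_file, warn = FALSE)[1]))
  unlink(port_file)
  if (is.na(port)) return(NULL)
  conn <- tryCatch(
    socketConnection("127.0.0.1", port, blocking = TRUE, open = "r+b",
                     timeout = 600),
    error = function(e) NULL, warning = function(w) NULL)
  conn
}

.chem_server_call <- function(payload) {
  if (isTRUE(.scafgen$server_disabled)) return(NULL)
  if (is.null(.scafgen$server)) {
    .scafgen$server <- .chem_server_start()
    if (is.null(.scafgen$server)) {
      .scafgen$server_disabled <- TRUE    # fall back to one-shot mode
      return(NULL)
    }
    reg.finalizer(.scafgen, function(e) {
      if (!is.null(e$server))
        try(close(e$server), silent = TRUE)
    }, onexit = TRUE)
  }
  line <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  res <- tryCatch({
    writeLines(line, .scafgen$server)
    flush(.scafgen$server)
    jsonlite::parse_json(readLines(.scafgen$server, n = 1))
  }, error = function(e) NULL)
  if (is.null(res)) {                     # server died; retry fresh once
    try(close(.scafgen$server), silent = TRUE)
    .scafgen$server <- NULL
    return(NULL)
  }
  if (!is.null(res$server_error))
    stop(sprintf("chemistry backend failed (op = '%s'): %s",
                 payload$op, res$server_error))
  res
}

#' Call the RDKit backend
#'
#' Low-level entry point used by every chemistry wrapper: sends a JSON
#' request to a persistent backend server (started on first use), falling
#' back to a fresh python process per batch where sockets are unavailable.
#'
#' @param op Operation name understood by the backend.
#' @param ... Request payload fields (vectors or lists).
#' @return Parsed response list.
#' @keywords internal
chem_call <- function(op, ...) {
  payload <- list(op = op, ...)
  res <- .chem_server_call(payload)
  if (!is.null(res)) return(res)
  req <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, out)), add = TRUE)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(python_bin(), c(chem_script(), req, out),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(out)) {
    stop(sprintf("chemistry backend failed (op = '%s', status = %s)", op,
                 status))
  }
  jsonlite::read_json(out, simplifyVector = FALSE)
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` where unparsable.
#' @export
#' @examples \dontrun{canonical_smiles(c("OCC", "C1=CC=CC=C1"))}
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- chem_call("canonical", smiles = as.list(as.character(smiles)))
  vapply(res$smiles, function(x) if (is.null(x)) NA_character_ else x, "")
}

#' Test whether SMILES strings parse
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# ECFP6 fingerprints as a list of sorted 0-based on-bit integer vectors
ecfp6_bits <- function(smiles) {
  if (length(smiles) == 0) return(list())
  res <- chem_call("ecfp6", smiles = as.list(as.character(smiles)))
  lapply(res$bits, function(b) {
    if (is.null(b)) NULL else as.integer(unlist(b))
  })
}
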