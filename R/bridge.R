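#' @keywords internal
"_PACKAGE"

# Bridge to the bundled RDKit worker. All chemistry primitives (SMILES/SMARTS/
# SMIRKS parsing, canonicalization, substructure matching, fingerprints,
# Murcko scaffolds) are delegated to RDKit through one batched JSON round trip
# per call; everything algorithmic lives in R on the returned graphs.

chem_python <- function() {
  getOption("rxnscout.python", Sys.getenv("RXNSCOUT_PYTHON", "python"))
}

chem_script <- function() {
  path <- pkg_file("python", "chembridge.py")
  if (!file.exists(path)) stop("chembridge.py not found")
  path
}

#' Run a batch of chemistry operations through the RDKit worker
#'
#' @param ops list of operation lists, each with an `op` field.
#' @return list of results, one per op; per-item errors are embedded.
#' @keywords internal
chem_call <- function(ops) {
  payload <- jsonlite::toJSON(list(ops = ops), auto_unbox = TRUE,
                              digits = NA, null = "null")
  out <- suppressWarnings(system2(
    chem_python(), shQuote(chem_script()),
    input = as.character(payload), stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry worker failed (exit ", status, ")")
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  lapply(res$results, function(r) {
    if (!is.null(r$error)) stop("chemistry worker: ", r$error)
    r$ok
  })
}

# Single-op convenience wrapper.
chem_call1 <- function(op) chem_call(list(op))[[1L]]
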