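# Named-reaction recognition via SMIRKS motifs.
#
# A motif matches when its reactant templates each hit a distinct reactant
# molecule AND forward application of the transformation enumerates a product
# whose canonical stereo-free SMILES equals a recorded product. This template
# application semantics (rather than two-sided substructure lookup) prevents
# false positives when reactant and product patterns would match unrelated
# sites. Naming never consults atom mapping.

#' Load a named-reaction SMIRKS motif library
#'
#' Reads a TSV with columns \code{name}, \code{smirks}, \code{class_hint},
#' \code{priority} (and optionally \code{example}, a Reaction SMILES the
#' motif is expected to fire on, used by the test suite). Malformed SMIRKS
#' rows are dropped with a row-numbered warning. The library iterates in
#' deterministic order: priority descending, then name ascending.
#'
#' @param path TSV path; default: the bundled library.
#' @return data.frame of class \code{rxn_motif_library}.
#' @export
load_motifs <- function(path = pkg_file("extdata", "reaction_motifs.tsv")) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  need <- c("name", "smirks", "class_hint", "priority")
  if (!all(need %in% names(df))) {
    stop("motif TSV must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df)) {
    chk <- chem_call1(list(op = "checksmirks", smirks = as.list(df$smirks)))
    ok <- vapply(chk, function(r) isTRUE(r$ok), logical(1))
    if (any(!ok)) {
      warning("dropping motif row(s) with malformed SMIRKS: ",
              paste(which(!ok), collapse = ", "))
      df <- df[ok, , drop = FALSE]
    }
  }
  if (!nrow(df)) stop("configuration error: no valid motifs in ", path)
  df <- df[order(-df$priority, df$name), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rxn_motif_library", "data.frame")
  df
}

#' Name a reaction against a motif library
#'
#' @param rxn an \code{rxn_reaction} (mapping not required).
#' @param lib an \code{rxn_motif_library}.
#' @return the highest-priority matching motif name, or \code{NA_character_}.
#' @export
name_reaction <- function(rxn, lib = load_motifs()) {
  name_reactions(list(rxn), lib)[[1L]]
}

#' Name many reactions in one worker round trip
#' @param rxns list of \code{rxn_reaction} objects.
#' @param lib an \code{rxn_motif_library}.
#' @return character vector of names (NA where no motif matches).
#' @export
name_reactions <- function(rxns, lib = load_motifs()) {
  if (!length(rxns)) return(character(0))
  jobs <- lapply(rxns, function(rxn) list(
    reactants = lapply(rxn$reactants, function(m) m$smiles),
    products = lapply(rxn$products, function(m) m$csmiles)))
  res <- chem_call1(list(op = "name", smirks = as.list(lib$smirks),
                         jobs = jobs))
  vapply(seq_along(rxns), function(k) {
    fired <- as.integer(unlist(res[[k]]$fired)) + 1L
    if (!length(fired)) return(NA_character_)
    lib$name[min(fired)]  # lib rows are already in priority order
  }, character(1))
}
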