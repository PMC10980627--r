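# Reaction SMILES parsing and the mapped-reaction data model.
#
# A reaction is stored as three lists of molecule graphs (reactants, agents,
# products). Each molecule is a list with the fields
#   smiles   - stereo-free SMILES retaining atom maps (round-trip stable)
#   csmiles  - canonical SMILES with maps removed
#   atoms    - data.frame(element, map, charge, aromatic, nh), 1-based rows
#   bonds    - data.frame(i, j, order2, aromatic); order2 = 2 x bond order
#   rings    - list of integer vectors (smallest set of smallest rings)
# Bond orders are kept as doubled integers throughout (aromatic bond = 3) so
# that all downstream matrix rules compare exact integers.

mol_from_bridge <- function(m) {
  atoms <- data.frame(
    element  = vapply(m$atoms, function(a) a$el, character(1)),
    map      = vapply(m$atoms, function(a) as.integer(a$map), integer(1)),
    charge   = vapply(m$atoms, function(a) as.integer(a$chg), integer(1)),
    aromatic = vapply(m$atoms, function(a) isTRUE(a$arom), logical(1)),
    nh       = vapply(m$atoms, function(a) as.integer(a$nh), integer(1)),
    stringsAsFactors = FALSE
  )
  bonds <- if (length(m$bonds)) {
    data.frame(
      i = vapply(m$bonds, function(b) as.integer(b[[1]]) + 1L, integer(1)),
      j = vapply(m$bonds, function(b) as.integer(b[[2]]) + 1L, integer(1)),
      order2 = vapply(m$bonds, function(b) as.integer(b[[3]]), integer(1)),
      aromatic = vapply(m$bonds, function(b) isTRUE(b[[4]]), logical(1))
    )
  } else {
    data.frame(i = integer(0), j = integer(0), order2 = integer(0),
               aromatic = logical(0))
  }
  rings <- lapply(m$rings, function(r) as.integer(unlist(r)) + 1L)
  list(smiles = m$smiles, csmiles = m$csmiles, atoms = atoms,
       bonds = bonds, rings = rings)
}

rxn_from_bridge <- function(parsed, source) {
  sides <- lapply(parsed[c("reactants", "agents", "products")],
                  function(side) lapply(side, mol_from_bridge))
  if (length(sides$reactants) == 0L || length(sides$products) == 0L) {
    stop("structure error: a reaction needs at least one reactant and one ",
         "product molecule (got '", source, "')")
  }
  side_maps <- function(mols) {
    m <- unlist(lapply(mols, function(x) x$atoms$map))
    sort(unique(m[m > 0L]))
  }
  universe <- sort(union(side_maps(sides$reactants), side_maps(sides$products)))
  # a map number present on both sides must refer to the same element
  elem_of <- function(mols) {
    a <- do.call(rbind, lapply(mols, function(x) x$atoms))
    a <- a[a$map > 0L, , drop = FALSE]
    stats::setNames(a$element, a$map)
  }
  er <- elem_of(sides$reactants); ep <- elem_of(sides$products)
  shared <- intersect(names(er), names(ep))
  bad <- shared[er[shared] != ep[shared]]
  if (length(bad)) {
    stop("mapping-conflict error: map number(s) ", paste(bad, collapse = ", "),
         " refer to different elements on the two sides")
  }
  structure(list(
    source_smiles = source,
    reactants = sides$reactants,
    agents = sides$agents,
    products = sides$products,
    map_universe = universe
  ), class = "rxn_reaction")
}

#' Parse a Reaction SMILES string into a mapped-reaction object
#'
#' Accepts both the two-segment form \code{"reactants>>products"} and the
#' three-segment form \code{"reactants>agents>products"}. Molecules are
#' sanitized (valence checked, aromaticity perceived) and stereochemistry is
#' stripped: enantiomers cannot be distinguished by the bond-electron matrix
#' formalism, so stereo descriptors never influence any downstream result.
#' Atom maps may be absent, partial, or present on one side only; the union of
#' all map numbers forms the matrix universe used by [build_be_matrix()].
#'
#' @param rsmiles a single Reaction SMILES string.
#' @return an object of class \code{rxn_reaction}.
#' @examples
#' \dontrun{
#' rxn <- parse_reaction(
#'   "[O:1]=[CH:2][c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1>>
#'    [OH:1][C:2](=[O:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1")
#' rxn$map_universe
#' }
#' @seealso [parse_reactions()] for the vectorized form.
#' @export
parse_reaction <- function(rsmiles) {
  parse_reactions(rsmiles)[[1L]]
}

#' Parse many Reaction SMILES in one worker round trip
#'
#' @param rsmiles character vector of Reaction SMILES.
#' @param .error how to handle per-reaction failures: \code{"stop"} (default)
#'   or \code{"keep"}, which stores a \code{try-error}-like condition message
#'   in place of the reaction.
#' @return list of \code{rxn_reaction} objects (or error messages).
#' @export
parse_reactions <- function(rsmiles, .error = c("stop", "keep")) {
  .error <- match.arg(.error)
  stopifnot(is.character(rsmiles))
  res <- chem_call1(list(op = "parse", rsmiles = as.list(rsmiles)))
  out <- vector("list", length(rsmiles))
  for (k in seq_along(rsmiles)) {
    r <- res[[k]]
    if (!is.null(r$error)) {
      msg <- paste0("parse error: ", r$error)
      if (.error == "stop") stop(msg) else out[[k]] <- structure(
        msg, class = "rxnscout_parse_error")
      next
    }
    parsed <- tryCatch(rxn_from_bridge(r, rsmiles[[k]]), error = function(e) e)
    if (inherits(parsed, "error")) {
      if (.error == "stop") stop(parsed) else out[[k]] <- structure(
        conditionMessage(parsed), class = "rxnscout_parse_error")
    } else out[[k]] <- parsed
  }
  out
}

#' @export
print.rxn_reaction <- function(x, ...) {
  cat("<rxn_reaction>\n")
  cat("  reactants:", length(x$reactants),
      " agents:", length(x$agents),
      " products:", length(x$products), "\n")
  cat("  mapped atoms:", length(x$map_universe), "\n")
  cat("  ", reaction_smiles(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a mapped reaction back to Reaction SMILES
#'
#' @param rxn an \code{rxn_reaction}.
#' @param agents include the agent segment if present.
#' @return a Reaction SMILES string.
#' @export
reaction_smiles <- function(rxn, agents = TRUE) {
  side <- function(mols) paste(vapply(mols, function(m) m$smiles,
                                      character(1)), collapse = ".")
  mid <- if (agents) side(rxn$agents) else ""
  paste0(side(rxn$reactants), ">", mid, ">", side(rxn$products))
}

#' Do all product heavy atoms carry atom maps?
#' @param rxn an \code{rxn_reaction}.
#' @return logical flag.
#' @export
is_fully_mapped <- function(rxn) {
  all(vapply(rxn$products, function(m) all(m$atoms$map > 0L), logical(1)))
}

#' Ensure a reaction carries atom maps, via a pluggable mapping provider
#'
#' If every product heavy atom already has a map number the reaction is
#' returned unchanged (the operation is idempotent). Otherwise the provider is
#' invoked on the source string; it must return a mapped Reaction SMILES.
#' No mapping model is bundled: mapping is an interface so that any external
#' atom-atom mapper can be plugged in.
#'
#' @param rxn an \code{rxn_reaction}.
#' @param mapper \code{NULL}, or a function \code{function(rsmiles) rsmiles}.
#' @return a fully mapped \code{rxn_reaction}.
#' @export
ensure_mapping <- function(rxn, mapper = NULL) {
  stopifnot(inherits(rxn, "rxn_reaction"))
  if (is_fully_mapped(rxn)) return(rxn)
  if (is.null(mapper)) {
    stop("reaction is not fully atom-mapped and no mapping provider is ",
         "configured; supply mapped input or pass a `mapper` function ",
         "(e.g. a wrapper around an external atom-atom mapping tool)")
  }
  mapped <- mapper(rxn$source_smiles)
  out <- parse_reaction(mapped)
  if (!is_fully_mapped(out)) {
    stop("mapping provider returned an incompletely mapped reaction")
  }
  out
}

#' Canonical identity key of a reaction
#'
#' Map-free, stereo-free canonical SMILES of the sorted reactants joined to
#' the sorted products. Identical chemistry yields an identical key regardless
#' of atom mapping, molecule order, or input stereo annotations; used for
#' deduplication during database ingestion.
#'
#' @param rxn an \code{rxn_reaction}.
#' @return a character key.
#' @export
canonical_reaction_key <- function(rxn) {
  side <- function(mols) paste(sort(vapply(mols, function(m) m$csmiles,
                                           character(1))), collapse = ".")
  paste0(side(rxn$reactants), ">>", side(rxn$products))
}
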