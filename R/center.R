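# Reaction-center extraction as valid Reaction SMILES.
#
# SMIRKS-style templates may contain half-open rings; a SMILES string may
# not. The extractor therefore starts from the transformation-matrix atoms
# (plus the atoms of participating functional groups), grows the requested
# number of bond shells, and then completes every ring system that has at
# least one included atom or is directly bonded to the selection, so the
# emitted fragments always re-parse.

# pure-R selection of the included atoms for one molecule
center_select_mol <- function(mol, cmaps, groups, ring_sets, radius) {
  amap <- mol$atoms$map
  sel <- which(amap %in% cmaps)
  for (g in groups) {
    if (any(amap[g$atoms] %in% cmaps)) sel <- union(sel, g$atoms)
  }
  b <- mol$bonds
  r <- radius
  while (r > 0L && length(sel)) {
    sel <- union(sel, c(b$j[b$i %in% sel], b$i[b$j %in% sel]))
    r <- r - 1L
  }
  if (length(sel)) {
    repeat {
      grew <- FALSE
      for (sys in ring_sets) {
        if (all(sys %in% sel)) next
        touched <- any(sys %in% sel)
        if (!touched) {
          nb <- c(b$j[b$i %in% sel], b$i[b$j %in% sel])
          touched <- any(nb %in% sys)
        }
        if (touched) { sel <- union(sel, sys); grew <- TRUE }
      }
      if (!grew) break
    }
  }
  sort(sel)
}

# batch variant: selections for all reactions first, then a single worker
# round trip for every fragment job
extract_centers_prepared <- function(rxns, ts, radius, groups_by_rxn,
                                     rings_by_rxn, sides_by_rxn) {
  selections <- vector("list", length(rxns))
  jobs <- list()
  slots <- list()  # (rxn k, molecule m) per job
  for (k in seq_along(rxns)) {
    t <- ts[[k]]
    if (!length(t$atom_order)) next
    mols <- c(rxns[[k]]$reactants, rxns[[k]]$products)
    ring_sets <- lapply(rings_by_rxn[[k]], function(ss)
      lapply(ss, function(s) s$member_atoms))
    sel <- lapply(seq_along(mols), function(m) {
      center_select_mol(mols[[m]], t$atom_order, groups_by_rxn[[k]][[m]],
                        ring_sets[[m]], radius)
    })
    selections[[k]] <- sel
    for (m in seq_along(mols)) {
      if (length(sel[[m]])) {
        jobs[[length(jobs) + 1L]] <- list(
          smiles = mols[[m]]$smiles,
          atoms = as.list(sel[[m]] - 1L), keep_maps = TRUE)
        slots[[length(slots) + 1L]] <- c(k, m)
      }
    }
  }
  frag <- if (length(jobs)) chem_call1(list(op = "frag", jobs = jobs)) else
    list()
  out <- vector("list", length(rxns))
  frag_by_rxn <- lapply(rxns, function(rxn)
    character(length(rxn$reactants) + length(rxn$products)))
  for (j in seq_along(jobs)) {
    k <- slots[[j]][1L]; m <- slots[[j]][2L]
    mols <- c(rxns[[k]]$reactants, rxns[[k]]$products)
    frag_by_rxn[[k]][m] <- frag[[j]]$smiles %||% mols[[m]]$smiles
  }
  for (k in seq_along(rxns)) {
    if (is.null(selections[[k]])) next
    sides <- sides_by_rxn[[k]]
    mols <- c(rxns[[k]]$reactants, rxns[[k]]$products)
    fs <- frag_by_rxn[[k]]
    maps <- sort(unique(unlist(lapply(seq_along(mols), function(m) {
      am <- mols[[m]]$atoms$map[selections[[k]][[m]]]
      am[am > 0L]
    }))))
    out[[k]] <- structure(list(
      radius = as.integer(radius),
      center_smiles = paste0(
        paste(fs[sides == "reactants" & nzchar(fs)], collapse = "."),
        ">>",
        paste(fs[sides == "products" & nzchar(fs)], collapse = ".")),
      included_atom_maps = maps
    ), class = "rxn_center")
  }
  out
}

extract_center_prepared <- function(rxn, t, radius, groups_k, rings_k,
                                    sides) {
  if (length(t$atom_order) == 0L) {
    stop("empty-center error: this reaction has no mapped transformation; ",
         "use the full reaction instead")
  }
  mols <- c(rxn$reactants, rxn$products)
  ring_sets <- lapply(rings_k, function(ss) lapply(ss, function(s)
    s$member_atoms))
  included <- lapply(seq_along(mols), function(m) {
    center_select_mol(mols[[m]], t$atom_order, groups_k[[m]],
                      ring_sets[[m]], radius)
  })
  jobs <- list(); where <- integer(0)
  for (m in seq_along(mols)) {
    if (length(included[[m]])) {
      jobs[[length(jobs) + 1L]] <- list(
        smiles = mols[[m]]$smiles,
        atoms = as.list(included[[m]] - 1L), keep_maps = TRUE)
      where <- c(where, m)
    }
  }
  res <- chem_call1(list(op = "frag", jobs = jobs))
  frag_smi <- character(length(mols))
  for (j in seq_along(where)) {
    frag_smi[where[j]] <- res[[j]]$smiles %||% mols[[where[j]]]$smiles
  }
  rside <- frag_smi[sides == "reactants" & nzchar(frag_smi)]
  pside <- frag_smi[sides == "products" & nzchar(frag_smi)]
  maps <- sort(unique(unlist(lapply(seq_along(mols), function(m) {
    am <- mols[[m]]$atoms$map[included[[m]]]
    am[am > 0L]
  }))))
  structure(list(
    radius = as.integer(radius),
    center_smiles = paste0(paste(rside, collapse = "."), ">>",
                           paste(pside, collapse = ".")),
    included_atom_maps = maps
  ), class = "rxn_center")
}

#' Extract the reaction center at a given atom radius
#'
#' Starts from the transformation-matrix atoms plus the atoms of
#' participating functional groups, grows \code{radius} bond shells, then
#' includes entire ring systems touched by (or directly bonded to) the
#' selection, and emits one valid mapped SMILES fragment per molecule with
#' hydrogens completed. Leaving-group atoms that appear in the
#' transformation matrix are included on the reactant side.
#'
#' @param rxn a mapped \code{rxn_reaction}.
#' @param t its \code{rxn_transformation}; computed if missing.
#' @param radius number of bond shells to grow (default 0: center atoms
#'   plus mandatory group/ring completion).
#' @param fg_defs functional-group table used for the completion rule.
#' @return an object of class \code{rxn_center}: \code{radius},
#'   \code{center_smiles} (valid Reaction SMILES, maps retained),
#'   \code{included_atom_maps} (a superset of the T-matrix atoms).
#' @export
extract_center <- function(rxn, t = transformation_matrix(rxn), radius = 0L,
                           fg_defs = load_functional_groups()) {
  stopifnot(radius >= 0L)
  mols <- c(rxn$reactants, rxn$products)
  sides <- rep(c("reactants", "products"),
               c(length(rxn$reactants), length(rxn$products)))
  groups <- detect_functional_groups_all(mols, fg_defs)
  rings <- extract_ring_systems_all(mols)
  extract_center_prepared(rxn, t, radius, groups, rings, sides)
}

#' @export
print.rxn_center <- function(x, ...) {
  cat("<rxn_center> radius ", x$radius, "\n  ", x$center_smiles, "\n",
      sep = "")
  invisible(x)
}
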