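# Functional groups, ring systems, formed rings, and Murcko scaffolds.

#' Load the functional-group SMARTS table
#'
#' Reads a TSV with columns \code{name} and \code{smarts}, validates every
#' pattern, attaches the pattern heavy-atom count as \code{size} and orders
#' the table by (size desc, name asc) -- the canonical tie-break order used
#' by the greedy overlap resolution in [detect_functional_groups()].
#'
#' @param path TSV path; default: the bundled 107-group table.
#' @return data.frame(name, smarts, size).
#' @export
load_functional_groups <- function(path = pkg_file(
  "extdata", "functional_groups.tsv")) {
  df <- read_pattern_tsv(path)
  chk <- chem_call1(list(op = "checksmarts", smarts = as.list(df$smarts)))
  ok <- vapply(chk, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) {
    stop("invalid SMARTS in functional-group table, row(s): ",
         paste(which(!ok), collapse = ", "))
  }
  df$size <- vapply(chk, function(r) as.integer(r$natoms), integer(1))
  df[order(-df$size, df$name), , drop = FALSE]
}

# greedy assignment over match candidates: larger patterns win, ties resolved
# by table order, then by first matched atom index
resolve_groups <- function(match_list, defs) {
  cand <- list()
  for (p in seq_along(match_list)) {
    for (hit in match_list[[p]]) {
      cand[[length(cand) + 1L]] <- list(
        p = p, atoms = sort(unique(hit)), first = min(hit))
    }
  }
  if (!length(cand)) return(list())
  sz <- vapply(cand, function(x) defs$size[x$p], integer(1))
  pp <- vapply(cand, function(x) x$p, integer(1))
  ff <- vapply(cand, function(x) x$first, integer(1))
  ord <- order(-sz, pp, ff)
  used <- integer(0)
  out <- list()
  for (k in ord) {
    a <- cand[[k]]$atoms
    if (any(a %in% used)) next
    used <- c(used, a)
    out[[length(out) + 1L]] <- list(name = defs$name[cand[[k]]$p], atoms = a)
  }
  out
}

#' Detect functional groups in a molecule
#'
#' Matches every pattern in the table and resolves overlaps greedily: each
#' atom belongs to at most one group, the largest pattern wins, ties go to
#' the canonical table order. Atom sets in the result are pairwise disjoint.
#'
#' @param mol a molecule list from a parsed reaction.
#' @param defs functional-group table from [load_functional_groups()].
#' @return list of \code{list(name, atoms)} with 1-based atom indices.
#' @export
detect_functional_groups <- function(mol, defs = load_functional_groups()) {
  detect_functional_groups_all(list(mol), defs)[[1L]]
}

#' Detect functional groups for many molecules in one worker round trip
#' @param mols list of molecule lists.
#' @param defs functional-group table.
#' @return list (per molecule) of lists \code{list(name, atoms)}.
#' @export
detect_functional_groups_all <- function(mols,
                                         defs = load_functional_groups()) {
  if (!length(mols)) return(list())
  matches <- molecule_matches(mols, defs$smarts)
  lapply(matches, resolve_groups, defs = defs)
}

HALOGENS <- c("F", "Cl", "Br", "I")

# ring systems as atom-index sets: fused/spiro rings sharing an atom are one
# system; substituent atoms are retained when they are terminal non-halogen
# heteroatoms on a ring atom, or exocyclic double-bond partners of one
ring_system_atoms <- function(mol) {
  rings <- mol$rings
  if (!length(rings)) return(list())
  systems <- list()
  for (r in rings) {
    merged <- FALSE
    for (k in seq_along(systems)) {
      if (length(intersect(systems[[k]], r))) {
        systems[[k]] <- union(systems[[k]], r)
        merged <- TRUE
        break
      }
    }
    if (!merged) systems[[length(systems) + 1L]] <- r
  }
  # transitive closure (a ring can bridge two previously separate systems)
  repeat {
    done <- TRUE
    if (length(systems) > 1L) {
      for (a in seq_len(length(systems) - 1L)) {
        for (b in (a + 1L):length(systems)) {
          if (length(intersect(systems[[a]], systems[[b]]))) {
            systems[[a]] <- union(systems[[a]], systems[[b]])
            systems[[b]] <- NULL
            done <- FALSE
            break
          }
        }
        if (!done) break
      }
    }
    if (done) break
  }
  b <- mol$bonds
  deg <- tabulate(c(b$i, b$j), nbins = nrow(mol$atoms))
  ring_atoms <- unique(unlist(rings))
  lapply(systems, function(sys) {
    keep <- sys
    for (k in seq_len(nrow(b))) {
      inA <- b$i[k] %in% sys; inB <- b$j[k] %in% sys
      if (inA == inB) next
      ring_end <- if (inA) b$i[k] else b$j[k]
      out_end <- if (inA) b$j[k] else b$i[k]
      if (out_end %in% ring_atoms) next        # linker to another system
      el <- mol$atoms$element[out_end]
      terminal_hetero <- deg[out_end] == 1L && !(el %in% HALOGENS) &&
        el != "C"
      exo_double <- b$order2[k] == 4L
      if (terminal_hetero || exo_double) keep <- c(keep, out_end)
    }
    sort(unique(keep))
  })
}

#' Extract the cleaned ring systems of a molecule
#'
#' Fused and spiro rings sharing atoms are merged into one system
#' (naphthalene is one system, never two benzenes). Substituents are removed
#' except terminal non-halogen heteroatoms bonded to a ring atom (phenol
#' oxygen) and exocyclic double-bond partners (a carbonyl oxygen on an
#' aliphatic ring); hydrogens are completed so every system is a closed-shell
#' molecule identified by its canonical SMILES.
#'
#' @param mol a molecule list.
#' @return list of \code{rxn_ring_system} objects: \code{canonical_smiles},
#'   \code{member_atoms} (1-based indices), \code{member_atom_maps}.
#' @export
extract_ring_systems <- function(mol) {
  extract_ring_systems_all(list(mol))[[1L]]
}

#' Vectorized ring-system extraction
#' @param mols list of molecule lists.
#' @return list (per molecule) of \code{rxn_ring_system} objects.
#' @export
extract_ring_systems_all <- function(mols) {
  sets <- lapply(mols, ring_system_atoms)
  jobs <- list()
  where <- list()
  for (m in seq_along(mols)) {
    for (s in seq_along(sets[[m]])) {
      jobs[[length(jobs) + 1L]] <- list(
        smiles = mols[[m]]$smiles,
        atoms = as.list(sets[[m]][[s]] - 1L))
      where[[length(where) + 1L]] <- c(m, s)
    }
  }
  out <- lapply(mols, function(x) list())
  if (length(jobs)) {
    res <- chem_call1(list(op = "frag", jobs = jobs))
    for (k in seq_along(jobs)) {
      m <- where[[k]][1L]; s <- where[[k]][2L]
      smi <- res[[k]]$smiles
      if (is.null(smi)) smi <- NA_character_  # cleanup failed; keep record
      atoms <- sets[[m]][[s]]
      out[[m]][[s]] <- structure(list(
        canonical_smiles = smi,
        member_atoms = atoms,
        member_atom_maps = sort(mols[[m]]$atoms$map[atoms][
          mols[[m]]$atoms$map[atoms] > 0L]),
        formed = FALSE
      ), class = "rxn_ring_system")
    }
  }
  out
}

#' Ring systems formed during a reaction
#'
#' A cleaned product ring system counts as formed when its canonical SMILES
#' occurs in no reactant; identical new systems are reported once with their
#' multiplicity. Comparison is on cleaned-system SMILES, so substituent
#' changes alone never create a formed ring.
#'
#' @param rxn an \code{rxn_reaction}.
#' @return data.frame(canonical_smiles, count).
#' @export
formed_rings <- function(rxn) {
  all_sys <- extract_ring_systems_all(c(rxn$reactants, rxn$products))
  nr <- length(rxn$reactants)
  formed_rings_from_systems(all_sys[seq_len(nr)], all_sys[-seq_len(nr)])
}

formed_rings_from_systems <- function(rsys, psys) {
  r_smi <- unlist(lapply(rsys, function(ss)
    vapply(ss, function(s) s$canonical_smiles, character(1))))
  p_smi <- unlist(lapply(psys, function(ss)
    vapply(ss, function(s) s$canonical_smiles, character(1))))
  new <- p_smi[!(p_smi %in% r_smi) & !is.na(p_smi)]
  if (!length(new)) {
    return(data.frame(canonical_smiles = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(new)
  data.frame(canonical_smiles = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Side chains are pruned until only ring and linker atoms (plus exocyclic
#' multiple-bond partners) remain. Acyclic molecules have an empty scaffold.
#'
#' @param mol a molecule list.
#' @return list(scaffold_smiles, is_acyclic_product).
#' @export
bemis_murcko_scaffold <- function(mol) {
  res <- chem_call1(list(op = "murcko", smiles = list(mol$smiles)))[[1L]]
  smi <- res$smiles %||% ""
  list(scaffold_smiles = smi, is_acyclic_product = !nzchar(smi))
}

#' Which functional groups and ring systems participate in the reaction
#' center?
#'
#' A group participates when at least one of its atoms appears in the
#' transformation matrix; a ring system participates when one of its member
#' atoms does, or when a participating group is directly bonded to one of
#' its ring atoms.
#'
#' @param groups per-molecule group lists for one side (with the molecule's
#'   atom maps available), as \code{list(mol, groups)} pairs; see
#'   [analyze()] for the assembled call.
#' @param rings per-molecule \code{rxn_ring_system} lists for the same side.
#' @param mols the molecule list itself.
#' @param t an \code{rxn_transformation}.
#' @return list(groups = character names, rings = character SMILES).
#' @export
participating_fragments <- function(groups, rings, mols, t) {
  cmaps <- t$atom_order
  part_groups <- character(0)
  part_group_atoms <- list()  # per molecule: atom indices of participating groups
  for (m in seq_along(mols)) {
    amap <- mols[[m]]$atoms$map
    part_group_atoms[[m]] <- integer(0)
    for (g in groups[[m]]) {
      if (any(amap[g$atoms] %in% cmaps)) {
        part_groups <- c(part_groups, g$name)
        part_group_atoms[[m]] <- c(part_group_atoms[[m]], g$atoms)
      }
    }
  }
  part_rings <- character(0)
  for (m in seq_along(mols)) {
    amap <- mols[[m]]$atoms$map
    b <- mols[[m]]$bonds
    for (s in rings[[m]]) {
      hit <- any(amap[s$member_atoms] %in% cmaps)
      if (!hit && length(part_group_atoms[[m]])) {
        nb <- c(b$j[b$i %in% part_group_atoms[[m]]],
                b$i[b$j %in% part_group_atoms[[m]]])
        hit <- any(nb %in% s$member_atoms)
      }
      if (hit && !is.na(s$canonical_smiles)) {
        part_rings <- c(part_rings, s$canonical_smiles)
      }
    }
  }
  list(groups = sort(unique(part_groups)), rings = sort(unique(part_rings)))
}
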