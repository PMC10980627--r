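# Rule-based reaction classification.
#
# A reaction is evaluated against an ordered cascade of ten class rules on
# its transformation matrix; the first matching rule wins. The cascade order
# exists because several classes share the same raw matrix signature (every
# constructive class is "a +1 somewhere"); the order plus a small set of
# exceptions resolves the overlaps. All bond-order deltas below are in
# chemical units (entries stored doubled are divided by 2 on extraction).

RXN_CLASSES <- c(
  "Aromatic Heterocycle Formation", "Acylation",
  "Functional Group Interconversion", "Reduction", "Oxidation",
  "Functional Group Addition", "C-C Coupling",
  "Heteroatom Alkylation and Arylation", "Protection", "Deprotection",
  "Miscellaneous"
)

HETEROATOMS <- c("N", "O", "S")  # bond-partner heteroatoms (rules 2/8/9/10)

read_pattern_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "smarts") %in% names(df)))
  df
}

#' Load the protecting-group SMARTS table
#' @param path TSV file with columns name, smarts; default: bundled table.
#' @return data.frame(name, smarts).
#' @export
load_protecting_groups <- function(path = pkg_file("extdata", "protecting_groups.tsv")) {
  read_pattern_tsv(path)
}

#' Load the carbon-balance exception SMARTS table
#' @param path TSV file with columns name, smarts; default: bundled table.
#' @return data.frame(name, smarts).
#' @export
load_carbon_balance_groups <- function(path = pkg_file("extdata", "carbon_balance_groups.tsv")) {
  read_pattern_tsv(path)
}

# ---- internal reaction indexing --------------------------------------------

# per-side lookup tables keyed by map number
side_index <- function(mols) {
  rows <- lapply(seq_along(mols), function(mi) {
    a <- mols[[mi]]$atoms
    keep <- a$map > 0L
    if (!any(keep)) return(NULL)
    data.frame(map = a$map[keep], mol = mi, idx = which(keep),
               element = a$element[keep], charge = a$charge[keep],
               aromatic = a$aromatic[keep], stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, rows)
  edges <- lapply(seq_along(mols), function(mi) {
    b <- mols[[mi]]$bonds
    m <- mols[[mi]]$atoms$map
    keep <- m[b$i] > 0L & m[b$j] > 0L
    if (!any(keep)) return(NULL)
    data.frame(mi = pmin(m[b$i[keep]], m[b$j[keep]]),
               mj = pmax(m[b$i[keep]], m[b$j[keep]]),
               order2 = b$order2[keep])
  })
  list(atoms = at, edges = do.call(rbind, edges), mols = mols)
}

rxn_index <- function(rxn) {
  list(r = side_index(rxn$reactants), p = side_index(rxn$products))
}

idx_element <- function(ix, map) {
  for (s in list(ix$r, ix$p)) {
    hit <- which(s$atoms$map == map)
    if (length(hit)) return(s$atoms$element[hit[1L]])
  }
  NA_character_
}

idx_order2 <- function(side, mi, mj) {
  e <- side$edges
  if (is.null(e)) return(0L)
  lo <- min(mi, mj); hi <- max(mi, mj)
  hit <- which(e$mi == lo & e$mj == hi)
  if (length(hit)) e$order2[hit[1L]] else 0L
}

# carbon double-bonded to O on either side of the reaction
is_acyl_carbon <- function(ix, map) {
  if (!identical(idx_element(ix, map), "C")) return(FALSE)
  for (s in list(ix$r, ix$p)) {
    e <- s$edges
    if (is.null(e)) next
    nb <- c(e$mj[e$mi == map & e$order2 == 4L],
            e$mi[e$mj == map & e$order2 == 4L])
    for (n in nb) {
      hit <- s$atoms$element[s$atoms$map == n]
      if (length(hit) && hit[1L] == "O") return(TRUE)
    }
  }
  FALSE
}

# carbon in a C#C triple bond on either side
is_alkyne_carbon <- function(ix, map) {
  if (!identical(idx_element(ix, map), "C")) return(FALSE)
  for (s in list(ix$r, ix$p)) {
    e <- s$edges
    if (is.null(e)) next
    nb <- c(e$mj[e$mi == map & e$order2 == 6L],
            e$mi[e$mj == map & e$order2 == 6L])
    for (n in nb) {
      hit <- s$atoms$element[s$atoms$map == n]
      if (length(hit) && hit[1L] == "C") return(TRUE)
    }
  }
  FALSE
}

# mapped heavy-atom neighbours of `map` on one side
idx_neighbours <- function(side, map) {
  e <- side$edges
  if (is.null(e)) return(integer(0))
  c(e$mj[e$mi == map], e$mi[e$mj == map])
}

# ---- bond change records ----------------------------------------------------

#' List the off-diagonal bond changes of a transformation matrix
#'
#' One record per changed atom pair (i < j by map number), annotated with the
#' context the classification rules consult: element identities, whether the
#' bond is newly formed (absent in reactants) or fully broken (absent in
#' products), acyl-carbon and alkyne-carbon character of each end, and
#' whether the delta is an aromatic-formation step (+0.5 or +1.5).
#'
#' @param t an \code{rxn_transformation}.
#' @param rxn the \code{rxn_reaction} it was derived from.
#' @return data.frame of bond-change records (zero rows for an empty center).
#' @export
bond_changes <- function(t, rxn) {
  ix <- rxn_index(rxn)
  n <- length(t$atom_order)
  recs <- list()
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        d2 <- t$entries[a, b]
        if (d2 == 0L) next
        mi <- t$atom_order[a]; mj <- t$atom_order[b]
        recs[[length(recs) + 1L]] <- data.frame(
          map_i = mi, map_j = mj, delta = d2 / 2,
          element_i = idx_element(ix, mi), element_j = idx_element(ix, mj),
          new_bond = idx_order2(ix$r, mi, mj) == 0L,
          broken_bond = idx_order2(ix$p, mi, mj) == 0L,
          acyl_i = is_acyl_carbon(ix, mi), acyl_j = is_acyl_carbon(ix, mj),
          alkyne_i = is_alkyne_carbon(ix, mi),
          alkyne_j = is_alkyne_carbon(ix, mj),
          hetero_i = idx_element(ix, mi) %in% HETEROATOMS,
          hetero_j = idx_element(ix, mj) %in% HETEROATOMS,
          aromatic_formation = (d2 == 1L || d2 == 3L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(recs)) do.call(rbind, recs) else data.frame(
    map_i = integer(0), map_j = integer(0), delta = numeric(0),
    element_i = character(0), element_j = character(0),
    new_bond = logical(0), broken_bond = logical(0),
    acyl_i = logical(0), acyl_j = logical(0),
    alkyne_i = logical(0), alkyne_j = logical(0),
    hetero_i = logical(0), hetero_j = logical(0),
    aromatic_formation = logical(0), stringsAsFactors = FALSE)
}

diag_changes <- function(t, rxn) {
  ix <- rxn_index(rxn)
  n <- length(t$atom_order)
  if (n == 0L) {
    return(data.frame(map = integer(0), delta = numeric(0),
                      element = character(0), stringsAsFactors = FALSE))
  }
  d <- diag(t$entries)
  keep <- which(d != 0L)
  data.frame(
    map = t$atom_order[keep], delta = d[keep] / 2,
    element = vapply(t$atom_order[keep], function(m) idx_element(ix, m),
                     character(1)),
    stringsAsFactors = FALSE)
}

# ---- carbon balance ---------------------------------------------------------

#' Is a reaction balanced in mapped carbon atoms?
#'
#' Modifying reaction classes (FGI, reduction, oxidation, FGA) conserve
#' carbon; an imbalance is tolerated only when every surplus carbon lies
#' inside a substructure from the allowed-group table (sulfonyl-type
#' fragments such as tosyl by default), so that e.g. a tosylation can still
#' count as a modifying reaction.
#'
#' @param rxn an \code{rxn_reaction}.
#' @param allowed_groups data.frame(name, smarts) of tolerated carbon donors.
#' @return logical flag.
#' @export
carbon_balanced <- function(rxn, allowed_groups = load_carbon_balance_groups()) {
  ix <- rxn_index(rxn)
  cr <- ix$r$atoms[ix$r$atoms$element == "C", , drop = FALSE]
  cp <- ix$p$atoms[ix$p$atoms$element == "C", , drop = FALSE]
  if (nrow(cr) == nrow(cp)) return(TRUE)
  # surplus carbons: map numbers present on one side only
  check_side <- function(side, mols, other_maps) {
    surplus <- side[!(side$map %in% other_maps), , drop = FALSE]
    if (nrow(surplus) == 0L) return(TRUE)
    matches <- molecule_matches(mols, allowed_groups$smarts)
    for (k in seq_len(nrow(surplus))) {
      covered <- FALSE
      for (m in matches[[surplus$mol[k]]]) {
        if (any(vapply(m, function(hit) surplus$idx[k] %in% hit, logical(1)))) {
          covered <- TRUE; break
        }
      }
      if (!covered) return(FALSE)
    }
    TRUE
  }
  check_side(cr, rxn$reactants, cp$map) &&
    check_side(cp, rxn$products, cr$map)
}

# SMARTS matches for a list of molecules: per molecule, per pattern, a list
# of 1-based atom index vectors
molecule_matches <- function(mols, smarts) {
  if (length(mols) == 0L || length(smarts) == 0L) {
    return(rep(list(rep(list(list()), length(smarts))), length(mols)))
  }
  res <- chem_call1(list(
    op = "match",
    smiles = lapply(mols, function(m) m$smiles),
    smarts = as.list(smarts)))
  lapply(res, function(molres) {
    lapply(molres$matches, function(hits) {
      if (!is.null(hits$error)) stop("invalid SMARTS in pattern table")
      lapply(hits, function(h) as.integer(unlist(h)) + 1L)
    })
  })
}

# is the mapped bond (mi, mj) inside a single protecting-group match on the
# given side?
in_pg_context <- function(side_ix, mols, pg_matches, mi, mj) {
  ai <- side_ix$atoms[side_ix$atoms$map == mi, , drop = FALSE]
  aj <- side_ix$atoms[side_ix$atoms$map == mj, , drop = FALSE]
  if (nrow(ai) == 0L || nrow(aj) == 0L) return(FALSE)
  if (ai$mol[1L] != aj$mol[1L]) return(FALSE)
  for (patt in pg_matches[[ai$mol[1L]]]) {
    for (hit in patt) {
      if (ai$idx[1L] %in% hit && aj$idx[1L] %in% hit) return(TRUE)
    }
  }
  FALSE
}

# ---- the cascade ------------------------------------------------------------

#' Classify a reaction into one of ten classes via the rule cascade
#'
#' Rules are evaluated in a fixed order (aromatic heterocycle formation,
#' acylation, functional group interconversion, reduction, oxidation,
#' functional group addition, C-C coupling, heteroatom alkylation and
#' arylation, protection, deprotection); the first match wins and anything
#' else is Miscellaneous. See the methods vignette for the exact predicates
#' and the exception set each rule carries.
#'
#' @param rxn an \code{rxn_reaction} (atom-mapped).
#' @param t its \code{rxn_transformation}; computed if missing.
#' @param protecting_groups,allowed_groups pattern tables; defaults bundled.
#' @return an object of class \code{rxn_classification} with fields
#'   \code{reaction_class}, \code{matched_rule}, \code{center_atoms},
#'   \code{notes}.
#' @export
classify <- function(rxn, t = transformation_matrix(rxn),
                     protecting_groups = load_protecting_groups(),
                     allowed_groups = load_carbon_balance_groups()) {
  classify_prepared(rxn, t, protecting_groups, allowed_groups)
}

# cascade core; pg_r / pg_p allow the batch pipeline to pass precomputed
# protecting-group matches
classify_prepared <- function(rxn, t, protecting_groups, allowed_groups,
                              pg_r = NULL, pg_p = NULL) {
  stopifnot(inherits(rxn, "rxn_reaction"), inherits(t, "rxn_transformation"))
  notes <- character(0)
  if (!is_fully_mapped(rxn)) notes <- c(notes, "low-confidence mapping")
  result <- function(class, rule) {
    structure(list(reaction_class = class, matched_rule = rule,
                   center_atoms = t$atom_order, notes = notes),
              class = "rxn_classification")
  }
  if (length(t$atom_order) == 0L) {
    notes <- c(notes, "no reaction center")
    return(result("Miscellaneous", "empty_center"))
  }

  ix <- rxn_index(rxn)
  ch <- bond_changes(t, rxn)
  dg <- diag_changes(t, rxn)
  ent <- t$entries
  off <- ent; diag(off) <- 0L
  if (is.null(pg_r)) {
    pg_r <- molecule_matches(rxn$reactants, protecting_groups$smarts)
  }
  if (is.null(pg_p)) {
    pg_p <- molecule_matches(rxn$products, protecting_groups$smarts)
  }

  hetero_broad <- function(el) !(el %in% c("C", "H"))  # FGA diagonal test
  cbal <- NULL
  is_cbal <- function() {
    if (is.null(cbal)) cbal <<- carbon_balanced(rxn, allowed_groups)
    cbal
  }

  # 1 -- aromatic heterocycle formation: a +0.5/+1.5 bond delta plus a
  #      product ring, containing a heteroatom, with new ring bonds
  if (any(ch$delta == 0.5 | ch$delta == 1.5)) {
    if (formed_hetero_ring(rxn, ix)) {
      return(result("Aromatic Heterocycle Formation",
                    "aromatic_heterocycle_formation"))
    }
  }

  # 2 -- acylation: new bond between an N/S nucleophile and an acyl carbon.
  #      O-acylations are esterifications, which follow the Protection
  #      convention; carbamate formation likewise defers to Protection; a
  #      product-only heteroatom is an oxidative addition, not an acylation.
  for (k in seq_len(nrow(ch))) {
    r <- ch[k, ]
    if (r$delta != 1 || !r$new_bond) next
    het <- if (r$hetero_i && r$acyl_j) "i" else if (r$hetero_j && r$acyl_i) "j"
           else next
    hmap <- if (het == "i") r$map_i else r$map_j
    hel <- if (het == "i") r$element_i else r$element_j
    amap <- if (het == "i") r$map_j else r$map_i
    if (!(hel %in% c("N", "S"))) next                 # O -> esterification
    if (!(hmap %in% ix$r$atoms$map)) {                # product-only atom
      notes <- c(notes, "acylation skipped: heteroatom absent in reactants")
      next
    }
    if (hel == "N" && carbamate_formed(ix, amap)) {
      notes <- c(notes, "carbamate exception")
      next
    }
    return(result("Acylation", "acylation"))
  }

  # 3 -- functional group interconversion: a center column exchanging only
  #      +1/-1 with non-carbon partners, carbon balanced; a carbon center
  #      gaining an N/O/S partner that already bears carbon is an
  #      alkylation/arylation and falls through
  for (a in seq_along(t$atom_order)) {
    col <- ent[, a]
    nz <- col[col != 0L]
    if (length(nz) == 0L) next
    if (sum(col) != 0L || !all(nz %in% c(-2L, 2L))) next
    center <- t$atom_order[a]
    partners_idx <- which(off[, a] != 0L)
    partners <- t$atom_order[partners_idx]
    pel <- vapply(partners, function(m) idx_element(ix, m), character(1))
    if (any(pel == "C")) next
    defer <- FALSE
    if (identical(idx_element(ix, center), "C")) {
      for (pi in seq_along(partners)) {
        if (off[partners_idx[pi], a] > 0L && pel[pi] %in% HETEROATOMS) {
          nbr <- idx_neighbours(ix$p, partners[pi])
          nbr <- setdiff(nbr, center)
          nel <- vapply(nbr, function(m) idx_element(ix, m), character(1))
          if (any(nel == "C")) { defer <- TRUE; break }
        }
      }
    }
    if (defer) next
    if (is_cbal()) {
      return(result("Functional Group Interconversion", "fgi"))
    }
  }

  pg_break <- function() {
    # a fully broken bond between a heteroatom/alkyne carbon and C/Si lying
    # inside a reactant-side protecting-group match
    for (k in seq_len(nrow(ch))) {
      r <- ch[k, ]
      if (r$delta >= 0 || !r$broken_bond) next
      ends_ok <- (((r$hetero_i || r$alkyne_i) &&
                     r$element_j %in% c("C", "Si")) ||
                  ((r$hetero_j || r$alkyne_j) &&
                     r$element_i %in% c("C", "Si")))
      if (!ends_ok) next
      if (in_pg_context(ix$r, rxn$reactants, pg_r, r$map_i, r$map_j)) {
        return(TRUE)
      }
    }
    FALSE
  }

  # 4 -- reduction: no bond-order increases; diagonal gains allowed only for
  #      atoms being deoxygenated (e.g. nitro -> amine); remaining nonzero
  #      diagonals must be oxygen; protecting-group cleavages defer to
  #      deprotection; carbon balanced
  if (all(off <= 0L) && any(ent != 0L)) {
    ok <- TRUE
    for (k in seq_len(nrow(dg))) {
      d <- dg[k, ]
      if (d$element == "O") next
      deox <- d$delta > 0 && any(
        ch$delta < 0 &
          ((ch$map_i == d$map & ch$element_j == "O") |
           (ch$map_j == d$map & ch$element_i == "O")))
      if (!deox) { ok <- FALSE; break }
    }
    if (ok && all(ch$delta <= 0) && !pg_break() && is_cbal()) {
      return(result("Reduction", "reduction"))
    }
  }

  # 5 -- oxidation: nonnegative T, nonzero diagonals only oxygen, and some
  #      positive entry involves an oxygen atom; carbon balanced
  if (all(ent >= 0L)) {
    diag_ok <- nrow(dg) == 0L || all(dg$element == "O")
    ox_involved <- any(dg$element == "O" & dg$delta > 0) ||
      any(ch$delta > 0 & (ch$element_i == "O" | ch$element_j == "O"))
    if (diag_ok && ox_involved && is_cbal()) {
      return(result("Oxidation", "oxidation"))
    }
  }

  # 6 -- functional group addition: nonnegative T with at least one nonzero
  #      heteroatom diagonal (any non-carbon element); carbon balanced
  if (all(ent >= 0L) && nrow(dg) > 0L &&
      all(vapply(dg$element, hetero_broad, logical(1))) && is_cbal()) {
    return(result("Functional Group Addition", "fga"))
  }

  # 7 -- carbon-carbon coupling: a new bond between two carbons
  if (any(ch$delta == 1 & ch$new_bond &
          ch$element_i == "C" & ch$element_j == "C")) {
    return(result("C-C Coupling", "cc_coupling"))
  }

  # 8 -- heteroatom alkylation and arylation: new bond between N/O/S and a
  #      non-acyl carbon
  for (k in seq_len(nrow(ch))) {
    r <- ch[k, ]
    if (r$delta != 1 || !r$new_bond) next
    if ((r$hetero_i && r$element_j == "C" && !r$acyl_j) ||
        (r$hetero_j && r$element_i == "C" && !r$acyl_i)) {
      return(result("Heteroatom Alkylation and Arylation",
                    "heteroatom_alkylation"))
    }
  }

  # 9 -- protection: new bond between a heteroatom or alkyne carbon and a
  #      carbon or silicon, inside a product-side protecting-group match
  for (k in seq_len(nrow(ch))) {
    r <- ch[k, ]
    if (r$delta != 1 || !r$new_bond) next
    ends_ok <- (((r$hetero_i || r$alkyne_i) &&
                   r$element_j %in% c("C", "Si")) ||
                ((r$hetero_j || r$alkyne_j) &&
                   r$element_i %in% c("C", "Si")))
    if (!ends_ok) next
    if (in_pg_context(ix$p, rxn$products, pg_p, r$map_i, r$map_j)) {
      return(result("Protection", "protection"))
    }
  }

  # 10 -- deprotection: nonpositive T and a protecting-group bond cleavage
  if (all(ent <= 0L) && pg_break()) {
    return(result("Deprotection", "deprotection"))
  }

  result("Miscellaneous", "miscellaneous")
}

# does the product contain a ring, with at least one non-carbon member, in
# which some ring bond is newly formed (or a ring atom did not exist as a
# mapped reactant atom)?
formed_hetero_ring <- function(rxn, ix = rxn_index(rxn)) {
  for (mol in rxn$products) {
    for (ring in mol$rings) {
      els <- mol$atoms$element[ring]
      if (!any(els != "C")) next
      maps <- mol$atoms$map[ring]
      if (any(maps > 0L & !(maps %in% ix$r$atoms$map))) return(TRUE)
      # ring bonds within this ring
      b <- mol$bonds
      inring <- b$i %in% ring & b$j %in% ring
      for (k in which(inring)) {
        mi <- mol$atoms$map[b$i[k]]; mj <- mol$atoms$map[b$j[k]]
        if (mi > 0L && mj > 0L && idx_order2(ix$r, mi, mj) == 0L) return(TRUE)
      }
    }
  }
  FALSE
}

# is the (product-side) acyl carbon `amap` part of a freshly closed
# N-C(=O)-O carbamate?
carbamate_formed <- function(ix, amap) {
  e <- ix$p$edges
  if (is.null(e)) return(FALSE)
  nb_maps <- c(e$mj[e$mi == amap], e$mi[e$mj == amap])
  nb_ord <- c(e$order2[e$mi == amap], e$order2[e$mj == amap])
  els <- vapply(nb_maps, function(m) {
    hit <- ix$p$atoms$element[ix$p$atoms$map == m]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  has_n <- any(els == "N" & nb_ord == 2L, na.rm = TRUE)
  has_o_single <- any(els == "O" & nb_ord == 2L, na.rm = TRUE)
  has_o_double <- any(els == "O" & nb_ord == 4L, na.rm = TRUE)
  isTRUE(has_n) && isTRUE(has_o_single) && isTRUE(has_o_double)
}

#' @export
print.rxn_classification <- function(x, ...) {
  cat("<rxn_classification>", x$reaction_class,
      " [rule:", x$matched_rule, "]\n")
  cat("  center atoms:", paste(x$center_atoms, collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
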