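# Bond-electron (BE) matrices in the Dugundji-Ugi formalism.
#
# A molecule side of a reaction is a symmetric N x N matrix over the union of
# atom-map numbers: off-diagonal entries hold bond orders (aromatic = 1.5),
# the diagonal holds the number of free unshared valence electrons. Entries
# are stored as integers equal to TWICE their chemical value so that the
# classification rules can compare exactly (+0.5 -> +1, aromatic -> 3);
# `as.matrix()` converts back to the chemical scale for display.

# main-group valence electron counts; elements outside this table cannot be
# placed on the matrix diagonal
GROUP_VALENCE <- c(
  Li = 1, Na = 1, K = 1,
  Be = 2, Mg = 2, Ca = 2, Zn = 2,
  B = 3, Al = 3,
  C = 4, Si = 4, Ge = 4, Sn = 4, Pb = 4,
  N = 5, P = 5, As = 5, Sb = 5,
  O = 6, S = 6, Se = 6, Te = 6,
  F = 7, Cl = 7, Br = 7, I = 7,
  H = 1
)

#' Free unshared valence electrons of a heavy atom
#'
#' Computed as (group valence electrons) - (sum of bond orders over all
#' neighbours, hydrogens included, aromatic bonds counted 1.5) - (formal
#' charge). The carbonyl oxygen of benzaldehyde gives 4, an aromatic benzene
#' carbon gives 0. Exotic valences that would go negative are clamped at zero
#' with a warning.
#'
#' @param mol a molecule list from [parse_reaction()].
#' @param idx atom index within the molecule.
#' @return a nonnegative integer.
#' @export
free_valence_electrons <- function(mol, idx) {
  a <- mol$atoms[idx, ]
  gv <- unname(GROUP_VALENCE[a$element])
  if (is.na(gv)) {
    stop("unsupported-element error: no group valence defined for '",
         a$element, "'")
  }
  gv <- as.integer(gv)
  b <- mol$bonds
  bsum2 <- sum(b$order2[b$i == idx | b$j == idx])  # doubled bond orders
  fe2 <- 2L * gv - bsum2 - 2L * a$nh - 2L * a$charge
  if (fe2 %% 2L != 0L) {
    # half-integer bookkeeping from the aromatic-1.5 convention (e.g. ring
    # fusion atoms sum to 4.5 bonds); round down
    fe2 <- fe2 - 1L
  }
  fe <- fe2 %/% 2L
  if (fe < 0L) {
    # aromatic fusion atoms legitimately dip just below zero under the 1.5
    # convention; anything else is an exotic valence worth flagging
    if (!(a$aromatic && fe >= -1L)) {
      warning("negative free-electron count for ", a$element, " atom ", idx,
              "; clamped to 0 (exotic valence)")
    }
    fe <- 0L
  }
  fe
}

#' Build the bond-electron matrix for one side of a reaction
#'
#' The matrix is indexed by the ascending map numbers of \code{universe};
#' atoms absent from this side (for unbalanced reactions) occupy all-zero
#' rows/columns, which is what makes bond cleavage to leaving groups visible
#' in the difference matrix. Unmapped atoms (spectators) are not represented.
#' Hydrogens never get rows; hydrogen-count changes surface only through the
#' heavy-atom free-electron values.
#'
#' @param molecules list of molecule lists (one side of an `rxn_reaction`).
#' @param universe integer vector of map numbers (the matrix index set).
#' @param side `"reactant"` or `"product"` (bookkeeping only).
#' @return an object of class \code{be_matrix} with fields \code{atom_order}
#'   (ascending map numbers), \code{entries} (integer matrix, doubled values)
#'   and \code{side}.
#' @export
build_be_matrix <- function(molecules, universe,
                            side = c("reactant", "product")) {
  side <- match.arg(side)
  universe <- sort(unique(as.integer(universe)))
  n <- length(universe)
  ent <- matrix(0L, n, n, dimnames = list(universe, universe))
  pos <- stats::setNames(seq_len(n), universe)
  seen <- integer(0)
  for (mol in molecules) {
    maps <- mol$atoms$map
    present <- which(maps > 0L & maps %in% universe)
    dup <- c(intersect(maps[present], seen),
             maps[present][duplicated(maps[present])])
    if (length(dup)) {
      stop("mapping-conflict error: duplicate map number(s) ",
           paste(dup, collapse = ", "), " on the ", side, " side")
    }
    seen <- c(seen, maps[present])
    for (idx in present) {
      p <- pos[[as.character(maps[idx])]]
      ent[p, p] <- 2L * free_valence_electrons(mol, idx)
    }
    b <- mol$bonds
    for (k in seq_len(nrow(b))) {
      mi <- maps[b$i[k]]; mj <- maps[b$j[k]]
      if (mi > 0L && mj > 0L && mi %in% universe && mj %in% universe) {
        p <- pos[[as.character(mi)]]; q <- pos[[as.character(mj)]]
        ent[p, q] <- b$order2[k]
        ent[q, p] <- b$order2[k]
      }
    }
  }
  structure(list(atom_order = universe, entries = ent, side = side),
            class = "be_matrix")
}

#' @export
as.matrix.be_matrix <- function(x, ...) x$entries / 2

#' @export
print.be_matrix <- function(x, ...) {
  cat("<be_matrix> side:", x$side, " dim:", length(x$atom_order), "\n")
  print(as.matrix(x))
  invisible(x)
}

#' Derive the R- and T-matrices of a reaction
#'
#' The R-matrix is the elementwise difference (product BE matrix) - (reactant
#' BE matrix); the transformation matrix T is the R-matrix with all-zero rows
#' and columns stripped, and identifies the reaction center. Atom order is
#' preserved (ascending map numbers).
#'
#' @param m_p product-side \code{be_matrix}.
#' @param m_r reactant-side \code{be_matrix}.
#' @return an object of class \code{rxn_transformation} with fields
#'   \code{atom_order} (retained map numbers), \code{entries} (stripped T,
#'   doubled integers), \code{full_r} and \code{full_order}.
#' @export
derive_transformation <- function(m_p, m_r) {
  stopifnot(inherits(m_p, "be_matrix"), inherits(m_r, "be_matrix"))
  if (!identical(m_p$atom_order, m_r$atom_order)) {
    stop("alignment error: the two BE matrices index different atom sets")
  }
  full_r <- m_p$entries - m_r$entries
  keep <- which(rowSums(full_r != 0L) > 0L | colSums(full_r != 0L) > 0L)
  structure(list(
    atom_order = m_p$atom_order[keep],
    entries = full_r[keep, keep, drop = FALSE],
    full_r = full_r,
    full_order = m_p$atom_order
  ), class = "rxn_transformation")
}

#' @export
as.matrix.rxn_transformation <- function(x, ...) x$entries / 2

#' @export
print.rxn_transformation <- function(x, ...) {
  cat("<rxn_transformation> center atoms:",
      paste(x$atom_order, collapse = ", "), "\n")
  if (length(x$atom_order)) print(as.matrix(x)) else cat("  (empty)\n")
  invisible(x)
}

#' Compute the transformation matrix of a mapped reaction
#'
#' Convenience wrapper: builds both BE matrices over the map universe and
#' subtracts them. Agents are excluded.
#'
#' @param rxn an \code{rxn_reaction}.
#' @return an \code{rxn_transformation}.
#' @export
transformation_matrix <- function(rxn) {
  stopifnot(inherits(rxn, "rxn_reaction"))
  m_r <- build_be_matrix(rxn$reactants, rxn$map_universe, "reactant")
  m_p <- build_be_matrix(rxn$products, rxn$map_universe, "product")
  derive_transformation(m_p, m_r)
}
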