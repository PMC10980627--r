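# One-call reaction analysis: parse -> matrices -> classify -> name ->
# fragments -> center -> fingerprint. `analyze_many()` is the batch
# workhorse (a handful of worker round trips for any number of reactions);
# `analyze()` is the single-reaction convenience wrapper.

#' Analyze a reaction end to end
#'
#' Runs the full pipeline on one Reaction SMILES (or pre-parsed reaction):
#' transformation matrix, rule-based classification, SMIRKS naming,
#' functional groups / rings / formed rings / scaffold, reaction-center
#' extraction and the reaction fingerprint. Chemically odd but parsable
#' input never raises: the result degrades to Miscellaneous with warnings.
#'
#' @param rsmiles Reaction SMILES string or an \code{rxn_reaction}.
#' @param mapper optional mapping provider for unmapped input (see
#'   [ensure_mapping()]); unmapped input without a provider is analyzed
#'   without matrix-based classification (named only).
#' @param radius center-extraction radius (bond shells).
#' @param motifs,fg_defs,protecting_groups,allowed_groups data tables;
#'   bundled defaults.
#' @param fp_scheme,fp_mode fingerprint configuration.
#' @return an object of class \code{rxn_analysis}.
#' @export
analyze <- function(rsmiles, mapper = NULL, radius = 0L,
                    motifs = load_motifs(),
                    fg_defs = load_functional_groups(),
                    protecting_groups = load_protecting_groups(),
                    allowed_groups = load_carbon_balance_groups(),
                    fp_scheme = "maccs", fp_mode = "concat") {
  rxn <- if (inherits(rsmiles, "rxn_reaction")) rsmiles else
    parse_reaction(rsmiles)
  if (!is.null(mapper) && !is_fully_mapped(rxn)) {
    rxn <- ensure_mapping(rxn, mapper)
  }
  analyze_many(list(rxn), radius = radius, motifs = motifs,
               fg_defs = fg_defs, protecting_groups = protecting_groups,
               allowed_groups = allowed_groups, fp_scheme = fp_scheme,
               fp_mode = fp_mode)[[1L]]
}

#' Analyze many parsed reactions in a fixed number of worker round trips
#'
#' @param rxns list of \code{rxn_reaction} objects.
#' @inheritParams analyze
#' @return list of \code{rxn_analysis} objects.
#' @export
analyze_many <- function(rxns, radius = 0L,
                         motifs = load_motifs(),
                         fg_defs = load_functional_groups(),
                         protecting_groups = load_protecting_groups(),
                         allowed_groups = load_carbon_balance_groups(),
                         fp_scheme = "maccs", fp_mode = "concat") {
  if (!length(rxns)) return(list())
  ts <- lapply(rxns, transformation_matrix)

  # flatten all molecules of all reactions for the batched fragment work
  mols_all <- list(); origin <- list()
  for (k in seq_along(rxns)) {
    for (side in c("reactants", "products")) {
      for (m in seq_along(rxns[[k]][[side]])) {
        mols_all[[length(mols_all) + 1L]] <- rxns[[k]][[side]][[m]]
        origin[[length(origin) + 1L]] <- list(k = k, side = side, m = m)
      }
    }
  }
  groups_all <- detect_functional_groups_all(mols_all, fg_defs)
  rings_all <- extract_ring_systems_all(mols_all)
  pg_all <- molecule_matches(mols_all, protecting_groups$smarts)

  per_rxn <- lapply(seq_along(rxns), function(k) {
    sel <- which(vapply(origin, function(o) o$k == k, logical(1)))
    sides <- vapply(origin[sel], function(o) o$side, character(1))
    list(idx = sel, sides = sides)
  })

  names_v <- name_reactions(rxns, motifs)
  fps <- reaction_fingerprints(rxns, fp_scheme, fp_mode)

  # Murcko scaffold of the main product (most heavy atoms, ties by
  # canonical SMILES order)
  main_prod <- vapply(rxns, function(rxn) {
    sizes <- vapply(rxn$products, function(m) nrow(m$atoms), integer(1))
    smis <- vapply(rxn$products, function(m) m$csmiles, character(1))
    ord <- order(-sizes, smis)
    smis[ord[1L]]
  }, character(1))
  sc <- chem_call1(list(op = "murcko", smiles = as.list(main_prod)))

  centers <- extract_centers_prepared(
    rxns, ts, radius,
    groups_by_rxn = lapply(per_rxn, function(p) groups_all[p$idx]),
    rings_by_rxn = lapply(per_rxn, function(p) rings_all[p$idx]),
    sides_by_rxn = lapply(per_rxn, function(p) p$sides))

  out <- vector("list", length(rxns))
  for (k in seq_along(rxns)) {
    out[[k]] <- tryCatch({
      rxn <- rxns[[k]]; t <- ts[[k]]
      idx <- per_rxn[[k]]$idx
      sides <- per_rxn[[k]]$sides
      groups_k <- groups_all[idx]
      rings_k <- rings_all[idx]
      nr <- sum(sides == "reactants")
      mols_k <- mols_all[idx]
      cls <- classify_prepared(
        rxn, t, protecting_groups, allowed_groups,
        pg_r = pg_all[idx][sides == "reactants"],
        pg_p = pg_all[idx][sides == "products"])
      part <- participating_fragments(groups_k, rings_k, mols_k, t)
      formed <- formed_rings_from_systems(
        rings_k[seq_len(nr)], rings_k[-seq_len(nr)])
      warn <- cls$notes
      center <- centers[[k]]
      if (length(t$atom_order) && is.null(center)) {
        warn <- c(warn, "center extraction failed")
      }
      smi <- sc[[k]]$smiles %||% ""
      structure(list(
        reaction_smiles = rxn$source_smiles,
        reaction_class = cls$reaction_class,
        matched_rule = cls$matched_rule,
        name = names_v[[k]],
        groups_in_center = part$groups,
        rings_in_center = part$rings,
        rings_formed = rep(formed$canonical_smiles, formed$count),
        scaffold = if (nzchar(smi)) smi else NA_character_,
        center = center,
        fingerprint = fps[[k]],
        warnings = warn
      ), class = "rxn_analysis")
    }, error = function(e) {
      structure(list(
        reaction_smiles = rxns[[k]]$source_smiles,
        reaction_class = "Miscellaneous",
        matched_rule = "error",
        name = names_v[[k]],
        groups_in_center = character(0),
        rings_in_center = character(0),
        rings_formed = character(0),
        scaffold = NA_character_,
        center = NULL,
        fingerprint = fps[[k]],
        warnings = paste("analysis error:", conditionMessage(e))
      ), class = "rxn_analysis")
    })
  }
  out
}

#' @export
print.rxn_analysis <- function(x, ...) {
  cat("<rxn_analysis>\n")
  cat("  class:   ", x$reaction_class, " [", x$matched_rule, "]\n", sep = "")
  cat("  name:    ", if (is.na(x$name)) "(unnamed)" else x$name, "\n",
      sep = "")
  cat("  groups in center:", paste(x$groups_in_center, collapse = ", "),
      "\n")
  cat("  rings in center: ", paste(x$rings_in_center, collapse = ", "),
      "\n")
  cat("  rings formed:    ",
      if (length(x$rings_formed)) paste(x$rings_formed, collapse = ", ")
      else "(none)", "\n")
  cat("  scaffold:", x$scaffold, "\n")
  if (!is.null(x$center)) cat("  center:  ", x$center$center_smiles, "\n")
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Serialize an analysis to stable key-sorted JSON
#'
#' @param x an \code{rxn_analysis}.
#' @param pretty pretty-print flag.
#' @return a JSON string.
#' @export
analysis_json <- function(x, pretty = TRUE) {
  stopifnot(inherits(x, "rxn_analysis"))
  payload <- list(
    center = if (is.null(x$center)) NULL else list(
      center_smiles = x$center$center_smiles,
      included_atom_maps = x$center$included_atom_maps,
      radius = x$center$radius),
    groups_in_center = as.list(x$groups_in_center),
    matched_rule = x$matched_rule,
    name = if (is.na(x$name)) NULL else x$name,
    reaction_class = x$reaction_class,
    reaction_smiles = x$reaction_smiles,
    rings_formed = as.list(x$rings_formed),
    rings_in_center = as.list(x$rings_in_center),
    scaffold = if (is.na(x$scaffold)) NULL else x$scaffold,
    warnings = as.list(x$warnings)
  )
  payload <- payload[order(names(payload))]
  jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA,
                   pretty = pretty)
}
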