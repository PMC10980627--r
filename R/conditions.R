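# Reaction condition suggestion by literature frequency.
#
# The retrieved precedent subset (same class/name/center annotation) is
# tallied per role (solvent, catalyst, reagent); the top-k names with their
# occurrence counts and frequency fractions form the suggestion. This is a
# purely frequency-based lookup over the database -- it knows nothing about
# solubility or compatibility of the species involved, and the output says
# so.

#' Load the condition-name synonym table
#' @param path TSV with columns variant, normalized.
#' @return data.frame(variant, normalized).
#' @export
load_condition_synonyms <- function(path = pkg_file(
  "extdata", "condition_synonyms.tsv")) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Normalize a solvent/catalyst/reagent name
#'
#' Trims, case-folds and whitespace-collapses the raw string, then applies a
#' small synonym table ("palladium(II) acetate" -> "Pd(OAc)2"). Placeholder
#' strings ("", "none", "-", "NA") normalize to \code{NA}.
#'
#' @param raw character vector of raw condition strings.
#' @param synonyms synonym table from [load_condition_synonyms()].
#' @return character vector of normalized names (NA for placeholders).
#' @export
normalize_condition_name <- function(raw, synonyms = load_condition_synonyms()) {
  x <- tolower(trimws(as.character(raw)))
  x <- gsub("\\s+", " ", x)
  x[x %in% c("", "none", "-", "na", "n/a")] <- NA_character_
  lut <- stats::setNames(synonyms$normalized, synonyms$variant)
  hit <- !is.na(x) & x %in% names(lut)
  out <- x
  out[hit] <- unname(lut[x[hit]])
  # unknown names keep their cleaned spelling
  out
}

tally_role <- function(values, k, synonyms, subset_size) {
  items <- unlist(lapply(values, function(v) {
    if (is.na(v) || !nzchar(v)) return(character(0))
    strsplit(v, ";", fixed = TRUE)[[1L]]
  }))
  items <- normalize_condition_name(items, synonyms)
  items <- items[!is.na(items)]
  if (!length(items)) {
    return(data.frame(name = character(0), count = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- table(items)
  df <- data.frame(name = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$name), , drop = FALSE]
  df <- utils::head(df, k)
  df$frequency <- df$count / subset_size
  rownames(df) <- NULL
  df
}

#' Suggest solvent, catalyst and reagent for a target reaction
#'
#' Retrieves the precedent subset for the query (tight or broad key; see
#' [search_similar()]) and reports the top-k most frequent normalized
#' condition names per role, with occurrence counts and frequency fractions
#' of the subset. Identical subsets always yield identical suggestions.
#'
#' @param db an annotated \code{rxn_database} with condition columns.
#' @param analysis an \code{rxn_analysis} of the query.
#' @param mode \code{"tight"} or \code{"broad"} subset key.
#' @param k entries per role (default 3).
#' @param synonyms condition synonym table.
#' @return an object of class \code{rxn_conditions}: \code{solvents},
#'   \code{catalysts}, \code{reagents} (ranked data.frames),
#'   \code{subset_size}, \code{mode}, \code{note}.
#' @export
suggest_conditions <- function(db, analysis, mode = c("tight", "broad"),
                               k = 3L, synonyms = load_condition_synonyms()) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "rxn_database"), inherits(analysis, "rxn_analysis"))
  tab <- db$records
  key <- switch(mode,
    tight = tight_key(analysis$reaction_class, analysis$name,
                      analysis$groups_in_center, analysis$rings_in_center),
    broad = broad_key(analysis$reaction_class, analysis$groups_in_center))
  sub <- tab[tab[[paste0(mode, "_key")]] == key, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) {
    message("empty precedent subset in ", mode, " mode")
  }
  grab <- function(col) if (col %in% names(sub)) sub[[col]] else
    rep(NA_character_, n)
  structure(list(
    solvents = tally_role(grab("solvent"), k, synonyms, max(n, 1L)),
    catalysts = tally_role(grab("catalyst"), k, synonyms, max(n, 1L)),
    reagents = tally_role(grab("reagent"), k, synonyms, max(n, 1L)),
    subset_size = n,
    mode = mode,
    note = paste("frequency-based suggestion from literature precedents;",
                 "solubility and compatibility are not modelled")
  ), class = "rxn_conditions")
}

#' @export
print.rxn_conditions <- function(x, ...) {
  cat("<rxn_conditions> subset of", x$subset_size, "precedents (",
      x$mode, "mode )\n")
  for (role in c("solvents", "catalysts", "reagents")) {
    cat(" ", role, ":\n")
    df <- x[[role]]
    if (!nrow(df)) { cat("    (none recorded)\n"); next }
    for (i in seq_len(nrow(df))) {
      cat(sprintf("    %-18s %3d  (%.0f%%)\n", df$name[i], df$count[i],
                  100 * df$frequency[i]))
    }
  }
  cat("  note:", x$note, "\n")
  invisible(x)
}
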