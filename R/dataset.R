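# Reaction database ingestion, annotation and persistence.
#
# A database is a data.frame of records plus a parallel fingerprint list and
# a config block (fingerprint scheme/mode, hashes of the motif and
# functional-group tables). Persistence is a plain CSV (fingerprints packed
# as sparse "bit:value" strings) with a JSON sidecar holding the config;
# searches refuse a query fingerprint that does not match the stored config,
# because a silent fingerprint mismatch corrupts every similarity value.

hash_strings <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

#' Ingest a reaction CSV into an (unannotated) reaction database
#'
#' Rows with unparsable Reaction SMILES are dropped and counted; duplicate
#' chemistry (identical canonical reaction key) is collapsed keeping the
#' first record, with condition strings merged. Unknown columns are carried
#' through untouched.
#'
#' @param path CSV file; must contain the Reaction SMILES column.
#' @param column_map named character vector mapping the roles
#'   \code{rsmiles}, \code{solvent}, \code{catalyst}, \code{reagent},
#'   \code{yield}, \code{reference} to CSV column names.
#' @return an object of class \code{rxn_database} (annotated = FALSE) with a
#'   \code{report} field: kept / dropped / merged / input_rows.
#' @export
ingest_csv <- function(path, column_map = c(
  rsmiles = "rsmiles", solvent = "solvent", catalyst = "catalyst",
  reagent = "reagent", yield = "yield", reference = "reference")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!(column_map[["rsmiles"]] %in% names(raw))) {
    stop("configuration error: Reaction SMILES column '",
         column_map[["rsmiles"]], "' not found in ", path)
  }
  n_in <- nrow(raw)
  for (role in c("solvent", "catalyst", "reagent", "yield", "reference")) {
    col <- column_map[role]
    if (!is.na(col) && col %in% names(raw) && col != role) {
      names(raw)[names(raw) == col] <- role
    }
  }
  names(raw)[names(raw) == column_map[["rsmiles"]]] <- "rsmiles"
  if (n_in == 0L) {
    warning("empty reaction CSV: ", path)
    db <- structure(list(
      records = cbind(data.frame(id = integer(0),
                                 canonical_key = character(0)), raw),
      rxns = list(), fingerprints = list(), config = NULL,
      annotated = FALSE,
      report = list(kept = 0L, dropped = 0L, merged = 0L, input_rows = 0L)),
      class = "rxn_database")
    return(db)
  }
  parsed <- parse_reactions(raw$rsmiles, .error = "keep")
  ok <- vapply(parsed, inherits, logical(1), "rxn_reaction")
  dropped <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  parsed <- parsed[ok]
  keys <- vapply(parsed, canonical_reaction_key, character(1))
  merged <- 0L
  keep <- !duplicated(keys)
  merge_cols <- intersect(c("solvent", "catalyst", "reagent", "reference"),
                          names(raw))
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    merged <- merged + length(idx) - 1L
    for (col in merge_cols) {
      vals <- unlist(strsplit(raw[[col]][idx], ";", fixed = TRUE))
      vals <- unique(vals[!is.na(vals) & nzchar(vals)])
      raw[[col]][idx[1L]] <- paste(vals, collapse = ";")
    }
  }
  raw <- raw[keep, , drop = FALSE]
  parsed <- parsed[keep]
  rec <- cbind(data.frame(id = seq_len(nrow(raw)),
                          canonical_key = keys[keep],
                          stringsAsFactors = FALSE), raw)
  if ("yield" %in% names(rec)) {
    rec$yield_percent <- suppressWarnings(as.numeric(rec$yield))
    rec$yield_percent[!is.na(rec$yield_percent) &
                        (rec$yield_percent < 0 |
                           rec$yield_percent > 100)] <- NA_real_
  }
  rownames(rec) <- NULL
  structure(list(
    records = rec, rxns = parsed, fingerprints = list(), config = NULL,
    annotated = FALSE,
    report = list(kept = nrow(rec), dropped = dropped, merged = merged,
                  input_rows = n_in)),
    class = "rxn_database")
}

#' @export
print.rxn_database <- function(x, ...) {
  cat("<rxn_database>", nrow(x$records), "records;",
      if (isTRUE(x$annotated)) "annotated" else "unannotated", "\n")
  if (!is.null(x$report)) {
    cat("  curation: kept", x$report$kept, "dropped", x$report$dropped,
        "merged", x$report$merged, "of", x$report$input_rows, "rows\n")
  }
  invisible(x)
}

#' Annotate a reaction database
#'
#' Every record gains its reaction class, name (or NA), participating
#' groups and rings, formed rings, product scaffold, reaction fingerprint
#' and the tight/broad subset keys. Per-record analysis failures degrade to
#' Miscellaneous with a warning and never abort the batch; re-running on an
#' annotated database reproduces the same result.
#'
#' @param db an \code{rxn_database} from [ingest_csv()].
#' @param motifs,fg_defs data tables; bundled defaults.
#' @param fp_scheme,fp_mode fingerprint configuration stored in the
#'   database config.
#' @param batch_size records analyzed per worker round trip.
#' @return the annotated \code{rxn_database}.
#' @export
annotate_database <- function(db, motifs = load_motifs(),
                              fg_defs = load_functional_groups(),
                              fp_scheme = "maccs", fp_mode = "concat",
                              batch_size = 200L) {
  stopifnot(inherits(db, "rxn_database"))
  n <- nrow(db$records)
  if (n == 0L) {
    db$annotated <- TRUE
    db$config <- list(fp_scheme = fp_scheme, fp_mode = fp_mode,
                      motif_hash = hash_strings(motifs$smirks),
                      fg_hash = hash_strings(fg_defs$smarts))
    return(db)
  }
  if (is.null(db$rxns) || !length(db$rxns)) {
    db$rxns <- parse_reactions(db$records$rsmiles)
  }
  analyses <- list()
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    analyses[idx] <- analyze_many(db$rxns[idx], motifs = motifs,
                                  fg_defs = fg_defs, fp_scheme = fp_scheme,
                                  fp_mode = fp_mode)
  }
  rec <- db$records
  rec$class <- vapply(analyses, function(a) a$reaction_class, character(1))
  rec$name <- vapply(analyses, function(a) a$name, character(1))
  rec$groups_in_center <- vapply(analyses, function(a)
    paste(a$groups_in_center, collapse = "|"), character(1))
  rec$rings_in_center <- vapply(analyses, function(a)
    paste(a$rings_in_center, collapse = "|"), character(1))
  rec$rings_formed <- vapply(analyses, function(a)
    paste(a$rings_formed, collapse = "|"), character(1))
  rec$scaffold <- vapply(analyses, function(a) a$scaffold, character(1))
  rec$tight_key <- vapply(analyses, function(a)
    tight_key(a$reaction_class, a$name, a$groups_in_center,
              a$rings_in_center), character(1))
  rec$broad_key <- vapply(analyses, function(a)
    broad_key(a$reaction_class, a$groups_in_center), character(1))
  db$records <- rec
  db$fingerprints <- lapply(analyses, function(a) a$fingerprint)
  db$analyses <- analyses
  db$config <- list(fp_scheme = fp_scheme, fp_mode = fp_mode,
                    motif_hash = hash_strings(motifs$smirks),
                    fg_hash = hash_strings(fg_defs$smarts))
  db$annotated <- TRUE
  db
}

pack_fp <- function(fp) {
  nz <- which(fp$vector != 0L)
  paste(paste0(nz, ":", fp$vector[nz]), collapse = ",")
}

unpack_fp <- function(s, scheme, mode) {
  base <- FP_BASE_LEN[[scheme]]
  len <- if (mode == "concat") 2L * base else base
  vec <- integer(len)
  if (!is.na(s) && nzchar(s)) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":",
                      fixed = TRUE)
    for (p in parts) vec[as.integer(p[1L])] <- as.integer(p[2L])
  }
  structure(list(scheme = scheme, mode = mode, vector = vec),
            class = "rxn_fingerprint")
}

#' Persist an annotated database (CSV + JSON config sidecar)
#' @param db annotated \code{rxn_database}.
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_reaction_db <- function(db, path) {
  stopifnot(isTRUE(db$annotated))
  rec <- db$records
  rec$fp <- vapply(db$fingerprints, pack_fp, character(1))
  utils::write.csv(rec, path, row.names = FALSE, na = "")
  jsonlite::write_json(db$config, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a persisted reaction database
#' @param path CSV path written by [write_reaction_db()].
#' @return an annotated \code{rxn_database}.
#' @export
read_reaction_db <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  fps <- lapply(rec$fp, unpack_fp, scheme = cfg$fp_scheme,
                mode = cfg$fp_mode)
  rec$fp <- NULL
  rec$name[is.na(rec$name)] <- NA_character_
  structure(list(records = rec, rxns = NULL, fingerprints = fps,
                 config = cfg, annotated = TRUE, report = NULL),
            class = "rxn_database")
}
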