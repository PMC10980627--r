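test_that("ingestion drops bad rows, merges duplicates, and reports counts", {
  f <- tempfile(fileext = ".csv")
  rows <- data.frame(
    rsmiles = c("CCO>>CC=O", "CCO>>CC=O",            # duplicate pair
                "OCC>>O=CC",                          # same chemistry again
                "not-a-smiles>>((",                   # invalid
                "CCBr.Oc1ccccc1>>CCOc1ccccc1",
                "O=Cc1ccccc1>>OCc1ccccc1",
                "CC(=O)O.OC>>COC(C)=O",
                "Nc1ccccc1>>O=[N+]([O-])c1ccccc1",
                "CCO>>CCBr",
                "c1ccccc1>>Brc1ccccc1"),
    solvent = c("THF", "DMF", "water", "x", "acetone", "MeOH", "MeOH",
                "AcOH", "water", "DCM"),
    stringsAsFactors = FALSE)
  write.csv(rows, f, row.names = FALSE)
  db <- ingest_csv(f)
  expect_equal(db$report$input_rows, 10L)
  expect_equal(db$report$dropped, 1L)
  expect_equal(db$report$merged, 2L)
  expect_equal(db$report$kept, 7L)
  expect_equal(nrow(db$records), 7L)
  expect_equal(db$report$kept + db$report$dropped + db$report$merged,
               db$report$input_rows)
  expect_false(any(duplicated(db$records$canonical_key)))
  # merged conditions concatenate the distinct values
  merged <- db$records$solvent[db$records$canonical_key ==
                                 canonical_reaction_key(
                                   parse_reaction("CCO>>CC=O"))]
  expect_setequal(strsplit(merged, ";")[[1]], c("THF", "DMF", "water"))
})

test_that("an empty CSV warns and yields an empty database", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(rsmiles = character(0)), f, row.names = FALSE)
  expect_warning(db <- ingest_csv(f), "empty")
  expect_equal(nrow(db$records), 0L)
})

test_that("a missing reaction column is a configuration error", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(foo = "CCO>>CC=O"), f, row.names = FALSE)
  expect_error(ingest_csv(f), "configuration error")
})

test_that("records without condition columns still annotate and search", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(rsmiles = c(FIXTURE_SMILES[["scheme1"]],
                                   FIXTURE_SMILES[["heck"]])),
            f, row.names = FALSE)
  db <- annotate_database(ingest_csv(f), motifs = fx_motifs(),
                          fg_defs = fx_fgdefs())
  expect_identical(db$records$class,
                   c("Oxidation", "C-C Coupling"))
  hits <- search_similar(db, db$analyses[[1L]], "full", threshold = 0)
  expect_equal(nrow(hits), 2L)
  s <- suggest_conditions(db, db$analyses[[2L]], mode = "tight")
  expect_equal(s$subset_size, 1L)
  expect_equal(nrow(s$catalysts), 0L)
})

test_that("annotation is deterministic and idempotent", {
  db1 <- fx_db()
  db2 <- annotate_database(db1, motifs = fx_motifs(),
                           fg_defs = fx_fgdefs())
  expect_identical(db1$records, db2$records)
  expect_identical(lapply(db1$fingerprints, function(f) f$vector),
                   lapply(db2$fingerprints, function(f) f$vector))
})

test_that("fixture generation is deterministic for a given seed", {
  f1 <- make_fixture_db(seed = 7L, n_per_class = 3L,
                        path = tempfile(fileext = ".csv"))
  f2 <- make_fixture_db(seed = 7L, n_per_class = 3L,
                        path = tempfile(fileext = ".csv"))
  expect_identical(readLines(f1), readLines(f2))
  f3 <- make_fixture_db(seed = 8L, n_per_class = 3L,
                        path = tempfile(fileext = ".csv"))
  expect_false(identical(readLines(f1), readLines(f3)))
  df <- read.csv(f1, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 30L)
  expect_equal(length(unique(df$true_class)), 10L)
})

test_that("a persisted database round-trips records and fingerprints", {
  db <- fx_db()
  path <- tempfile(fileext = ".csv")
  write_reaction_db(db, path)
  back <- read_reaction_db(path)
  expect_identical(back$config$fp_scheme, db$config$fp_scheme)
  expect_equal(nrow(back$records), nrow(db$records))
  expect_identical(back$records$tight_key, db$records$tight_key)
  for (k in c(1L, 10L, 20L)) {
    expect_identical(back$fingerprints[[k]]$vector,
                     db$fingerprints[[k]]$vector)
  }
  # searches over the reloaded database match the in-memory ones
  q <- db$analyses[[5L]]
  h1 <- search_similar(db, q, "broad", threshold = 0)
  h2 <- search_similar(back, q, "broad", threshold = 0)
  expect_identical(h1$id, h2$id)
  expect_equal(h1$similarity, h2$similarity)
})

test_that("analysis JSON carries the committed schema's required fields", {
  schema <- jsonlite::read_json(system.file("schema",
                                            "analysis-schema.json",
                                            package = "rxnscout"))
  a <- analyze(fx_rxn("scheme1"), motifs = fx_motifs(),
               fg_defs = fx_fgdefs())
  payload <- jsonlite::parse_json(analysis_json(a))
  for (req in unlist(schema$required)) {
    expect_true(req %in% names(payload), info = req)
  }
  expect_true(payload$reaction_class %in%
                unlist(schema$properties$reaction_class$enum))
})

test_that("the command-line wrapper classifies to JSON", {
  cli <- system.file("cli", "rxnscout", package = "rxnscout")
  out <- suppressWarnings(system2("Rscript", c(
    cli, "classify", shQuote(FIXTURE_SMILES[["scheme1"]])),
    stdout = TRUE, stderr = FALSE))
  payload <- jsonlite::parse_json(paste(out, collapse = ""))
  expect_identical(payload$class, "Oxidation")
})
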