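bitfp <- function(bits, scheme = "maccs", mode = "concat", len = 332L) {
  v <- integer(len); v[bits] <- 1L
  structure(list(scheme = scheme, mode = mode, vector = v),
            class = "rxn_fingerprint")
}

test_that("fingerprint shapes follow scheme and combination mode", {
  rxn <- fx_rxn("scheme1")
  expect_length(reaction_fingerprint(rxn, "maccs", "concat")$vector, 332L)
  expect_length(reaction_fingerprint(rxn, "ecfp4", "concat")$vector, 2048L)
  expect_length(reaction_fingerprint(rxn, "maccs", "sum")$vector, 166L)
  ident <- reaction_fingerprint(fx_rxn("identity_mapped"), "maccs",
                                "difference")
  expect_true(all(ident$vector == 0L))
  expect_true(any(reaction_fingerprint(rxn, "maccs",
                                       "difference")$vector != 0L))
})

test_that("tanimoto has identity, symmetry, range, and the exact 1/3 case", {
  a <- bitfp(c(1, 2), len = 3); b <- bitfp(c(1, 3), len = 3)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(bitfp(1:5, len = 20), bitfp(6:9, len = 20)), 0)
  expect_equal(tanimoto(bitfp(integer(0)), bitfp(integer(0))), 1)
  fps <- reaction_fingerprints(lapply(c("scheme1", "heck", "amide",
                                        "benzothiazole"), fx_rxn))
  for (i in seq_along(fps)) {
    for (j in seq_along(fps)) {
      s <- tanimoto(fps[[i]], fps[[j]])
      expect_identical(s, tanimoto(fps[[j]], fps[[i]]))
      expect_gte(s, 0); expect_lte(s, 1)
      if (i == j) expect_equal(s, 1)
    }
  }
  expect_error(tanimoto(bitfp(1, scheme = "maccs"),
                        bitfp(1, scheme = "ecfp4", len = 332L)),
               "incompatibility")
})

test_that("search modes nest: tight within broad within full", {
  db <- fx_db()
  for (row in c(1L, 8L, 15L, 25L)) {
    q <- db$analyses[[row]]
    tight <- search_similar(db, q, "tight", threshold = 0, k = 100L)
    broad <- search_similar(db, q, "broad", threshold = 0, k = 100L)
    full <- search_similar(db, q, "full", threshold = 0, k = 100L)
    expect_true(all(tight$id %in% broad$id), info = row)
    expect_true(all(broad$id %in% full$id), info = row)
    expect_equal(nrow(full), nrow(db$records))
  }
})

test_that("a verbatim database reaction is its own top hit at similarity 1", {
  db <- fx_db()
  q <- db$analyses[[3L]]
  hits <- search_similar(db, q, "tight", threshold = 0)
  expect_equal(hits$id[1L], db$records$id[3L])
  expect_equal(hits$similarity[1L], 1)
  expect_true(all(diff(hits$similarity) <= 0))
})

test_that("a pyridine-bearing precedent needs the broadened search", {
  db <- fx_db()
  bt_rows <- which(db$records$true_class == "Aromatic Heterocycle Formation")
  rings <- db$records$rings_in_center[bt_rows]
  pyridine_row <- bt_rows[grepl("c1ccncc1", rings)]
  expect_length(pyridine_row, 1L)
  q <- db$analyses[[bt_rows[1L]]]  # plain phenyl query
  tight <- search_similar(db, q, "tight", threshold = 0, k = 100L)
  broad <- search_similar(db, q, "broad", threshold = 0, k = 100L)
  expect_false(db$records$id[pyridine_row] %in% tight$id)
  expect_true(db$records$id[pyridine_row] %in% broad$id)
  expect_true(all(tight$id %in% broad$id))
})

test_that("an empty candidate subset returns empty with a diagnostic", {
  db <- fx_db()
  q <- analyze(fx_rxn("tosylation"), motifs = fx_motifs(),
               fg_defs = fx_fgdefs())
  expect_message(hits <- search_similar(db, q, "tight"), "broader")
  expect_equal(nrow(hits), 0L)
})

test_that("MACCS similarities run higher than ECFP4 as a trend", {
  db <- fx_db()
  rxns <- parse_reactions(db$records$rsmiles[1:12])
  fps_m <- reaction_fingerprints(rxns, "maccs", "concat")
  fps_e <- reaction_fingerprints(rxns, "ecfp4", "concat")
  pair_mean <- function(fps) {
    s <- c()
    for (i in 1:11) for (j in (i + 1):12) {
      s <- c(s, tanimoto(fps[[i]], fps[[j]]))
    }
    mean(s)
  }
  expect_gt(pair_mean(fps_m), pair_mean(fps_e))
})
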