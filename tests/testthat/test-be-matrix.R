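# frozen expected values from the worked benzaldehyde -> benzoic acid
# example: the 9x9 matrices, their difference, and the stripped 2x2 center

scheme1_expected_mr <- function() {
  u <- as.character(1:9)
  m <- matrix(0, 9, 9, dimnames = list(u, u))
  m["1", "1"] <- 4
  m["1", "2"] <- 2; m["2", "1"] <- 2
  m["2", "4"] <- 1; m["4", "2"] <- 1
  ring <- c(4, 5, 6, 7, 8, 9, 4)
  for (k in 1:6) {
    a <- as.character(ring[k]); b <- as.character(ring[k + 1])
    m[a, b] <- 1.5; m[b, a] <- 1.5
  }
  m
}

test_that("free valence electron counts follow the closed-shell formula", {
  benzaldehyde <- fx_rxn("scheme1")$reactants[[1]]
  o_idx <- which(benzaldehyde$atoms$map == 1L)
  expect_identical(free_valence_electrons(benzaldehyde, o_idx), 4L)
  arom_idx <- which(benzaldehyde$atoms$map == 5L)
  expect_identical(free_valence_electrons(benzaldehyde, arom_idx), 0L)
  benzoic <- fx_rxn("scheme1")$products[[1]]
  oh_idx <- which(benzoic$atoms$map == 3L)
  expect_identical(free_valence_electrons(benzoic, oh_idx), 4L)
  # charged nitrogen: quaternary-style nitro nitrogen has no lone pair
  nitro <- fx_rxn("nitro_reduction")$reactants[[1]]
  n_idx <- which(nitro$atoms$map == 2L)
  expect_identical(free_valence_electrons(nitro, n_idx), 0L)
})

test_that("unsupported elements on the diagonal raise an element error", {
  rxn <- parse_reaction("[U:1]>>[U:1]")
  expect_error(build_be_matrix(rxn$reactants, rxn$map_universe, "reactant"),
               "unsupported-element")
})

test_that("the worked example reproduces both BE matrices entry for entry", {
  rxn <- fx_rxn("scheme1")
  m_r <- build_be_matrix(rxn$reactants, rxn$map_universe, "reactant")
  m_p <- build_be_matrix(rxn$products, rxn$map_universe, "product")
  exp_r <- scheme1_expected_mr()
  expect_equal(unname(as.matrix(m_r)), unname(exp_r))
  # the product side adds the new C2-O3 bond, its 4 free electrons, and the
  # rest is unchanged
  exp_p <- exp_r
  exp_p["2", "3"] <- 1; exp_p["3", "2"] <- 1; exp_p["3", "3"] <- 4
  expect_equal(unname(as.matrix(m_p)), unname(exp_p))
  # row/column of the product-only oxygen is all zero on the reactant side
  expect_true(all(as.matrix(m_r)[3, ] == 0))
  expect_true(all(as.matrix(m_r)[, 3] == 0))
})

test_that("the difference matrix strips to the printed 2x2 center", {
  rxn <- fx_rxn("scheme1")
  t <- transformation_matrix(rxn)
  expect_identical(t$atom_order, c(2L, 3L))
  expect_equal(unname(as.matrix(t)), matrix(c(0, 1, 1, 4), 2, 2))
  # full R is zero outside the center
  full <- t$full_r / 2
  expect_equal(sum(full != 0), 3)
})

test_that("degenerate inputs give empty or zero matrices", {
  ident <- fx_rxn("identity_mapped")
  t <- transformation_matrix(ident)
  expect_length(t$atom_order, 0L)
  expect_true(all(t$full_r == 0L))
  z <- build_be_matrix(list(), 1:3, "reactant")
  expect_equal(unname(as.matrix(z)), matrix(0, 3, 3))
})

test_that("amide formation shows the +1/-1 exchange at the acyl carbon", {
  t <- transformation_matrix(fx_rxn("amide"))
  m <- as.matrix(t)
  o <- as.character(t$atom_order)
  get <- function(i, j) m[which(o == i), which(o == j)]
  expect_equal(get("1", "10"), 1)   # new N-C(acyl) bond
  expect_equal(get("1", "3"), -1)   # broken C-OH bond
})

test_that("duplicate map numbers on one side are a mapping conflict", {
  rxn <- parse_reaction("[CH3:1][CH3:1]>>[CH3:1][CH3:2]")
  expect_error(build_be_matrix(rxn$reactants, rxn$map_universe, "reactant"),
               "mapping-conflict")
})

test_that("mismatched atom sets cannot be subtracted", {
  rxn <- fx_rxn("scheme1")
  m_r <- build_be_matrix(rxn$reactants, rxn$map_universe, "reactant")
  m_p <- build_be_matrix(rxn$products, 1:8, "product")
  expect_error(derive_transformation(m_p, m_r), "alignment")
})

test_that("T equals the independent brute-force oracle on randomized cases", {
  pool <- random_fixture_pool(200L, seed = 11L)
  rxns <- parse_reactions(pool)
  for (k in seq_along(rxns)) {
    t <- transformation_matrix(rxns[[k]])
    o <- oracle_T(rxns[[k]])
    expect_identical(t$atom_order, o$atoms, info = paste("case", k))
    expect_equal(unname(as.matrix(t)), unname(o$entries),
                 info = paste("case", k))
    # symmetry and the half-integer grid
    expect_true(isSymmetric(t$entries), info = paste("case", k))
    expect_true(all(t$entries == round(t$entries)),
                info = paste("case", k))
  }
})

test_that("atom-map relabeling permutes T without changing its content", {
  for (nm in c("scheme1", "heck", "boc_protection", "benzothiazole")) {
    rl <- relabel_maps(FIXTURE_SMILES[[nm]], seed = 5L)
    t0 <- transformation_matrix(fx_rxn(nm))
    t1 <- transformation_matrix(parse_reaction(rl$rsmiles))
    mapped_atoms <- sort(unname(rl$perm[as.character(t0$atom_order)]))
    expect_identical(t1$atom_order, as.integer(mapped_atoms), info = nm)
    # same multiset of entries
    expect_equal(sort(as.vector(as.matrix(t1))),
                 sort(as.vector(as.matrix(t0))), info = nm)
  }
})
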