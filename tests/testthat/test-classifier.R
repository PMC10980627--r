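test_that("bond changes carry the context flags the rules consult", {
  rxn <- fx_rxn("scheme1")
  ch <- bond_changes(transformation_matrix(rxn), rxn)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$map_i, 2L)
  expect_equal(ch$map_j, 3L)
  expect_equal(ch$delta, 1)
  expect_true(ch$new_bond)
  expect_true(ch$acyl_i)      # C2 is double-bonded to O1 on both sides
  expect_true(ch$hetero_j)    # O3
  hk <- fx_rxn("heck")
  chh <- bond_changes(transformation_matrix(hk), hk)
  cc <- chh[chh$delta == 1, ]
  expect_equal(nrow(cc), 1L)
  expect_identical(sort(c(cc$element_i, cc$element_j)), c("C", "C"))
  ident <- bond_changes(transformation_matrix(fx_rxn("identity_mapped")),
                        fx_rxn("identity_mapped"))
  expect_equal(nrow(ident), 0L)
})

test_that("carbon balance holds exactly or via the sulfonyl exceptions", {
  expect_true(carbon_balanced(fx_rxn("scheme1")))
  # tosylation: seven tosyl carbons appear only on the product side but are
  # fully attributable to the tosyl exception pattern
  expect_true(carbon_balanced(fx_rxn("tosylation")))
  # a partially mapped coupling gains ring carbons with no exception
  partial <- parse_reaction(paste0(
    "[Br:20][c:1]1[cH:2][cH:3][cH:4][cH:5][n:6]1.OB(O)c1ccccc1>>",
    "[c:1]1([c:7]2[cH:8][cH:9][cH:10][cH:11][cH:12]2)[cH:2][cH:3][cH:4]",
    "[cH:5][n:6]1"))
  expect_false(carbon_balanced(partial))
})

test_that("each class anchor lands on its rule in cascade order", {
  cases <- c(
    scheme1 = "Oxidation",
    suzuki_mapped = "C-C Coupling",
    heck = "C-C Coupling",
    amide = "Acylation",
    boc_protection = "Protection",
    boc_deprotection = "Deprotection",
    friedel_crafts = "C-C Coupling",
    williamson = "Heteroatom Alkylation and Arylation",
    nitro_reduction = "Reduction",
    alcohol_oxidation = "Oxidation",
    bromination = "Functional Group Addition",
    fgi_bromide = "Functional Group Interconversion",
    benzothiazole = "Aromatic Heterocycle Formation",
    esterification = "Protection"
  )
  for (nm in names(cases)) {
    cl <- classify(fx_rxn(nm))
    expect_identical(cl$reaction_class, unname(cases[[nm]]), info = nm)
  }
  # the Boc case documents why it is not an acylation
  cl <- classify(fx_rxn("boc_protection"))
  expect_true("carbamate exception" %in% cl$notes)
})

test_that("an empty center is Miscellaneous with an explanatory note", {
  cl <- classify(fx_rxn("identity_mapped"))
  expect_identical(cl$reaction_class, "Miscellaneous")
  expect_true("no reaction center" %in% cl$notes)
  expect_length(cl$center_atoms, 0L)
})

test_that("center atoms reported equal the stripped matrix index set", {
  for (nm in c("scheme1", "heck", "benzothiazole")) {
    t <- transformation_matrix(fx_rxn(nm))
    cl <- classify(fx_rxn(nm), t)
    expect_identical(cl$center_atoms, t$atom_order, info = nm)
  }
})

test_that("classification is deterministic and invariant to relabeling and
           reactant order", {
  for (nm in c("scheme1", "suzuki_mapped", "amide", "boc_protection",
               "williamson", "nitro_reduction", "benzothiazole",
               "fgi_bromide")) {
    base <- classify(fx_rxn(nm))$reaction_class
    again <- classify(fx_rxn(nm))$reaction_class
    expect_identical(base, again, info = nm)
    var <- permute_reactants(
      relabel_maps(FIXTURE_SMILES[[nm]], seed = 42L)$rsmiles, seed = 43L)
    expect_identical(classify(parse_reaction(var))$reaction_class, base,
                     info = nm)
  }
})

test_that("partially mapped reactions classify with a low-confidence note", {
  partial <- parse_reaction(
    "[CH3:1][OH:2]>>[CH3:1][O:2]C")  # product carries an unmapped methyl
  cl <- classify(partial)
  expect_true("low-confidence mapping" %in% cl$notes)
})
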