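mol_of <- function(smiles) {
  parse_reaction(paste0(smiles, ">>", smiles))$reactants[[1]]
}

test_that("the functional-group table loads validated and size-ordered", {
  defs <- fx_fgdefs()
  expect_equal(nrow(defs), 107L)
  expect_true(all(diff(defs$size) <= 0))
})

test_that("group detection resolves overlaps toward the larger pattern", {
  defs <- fx_fgdefs()
  hits <- detect_functional_groups(mol_of("O=Cc1ccccc1"), defs)
  expect_equal(vapply(hits, function(h) h$name, character(1)), "aldehyde")
  # benzoic acid: the carboxylic acid wins, no ketone is reported
  hits <- detect_functional_groups(mol_of("OC(=O)c1ccccc1"), defs)
  nms <- vapply(hits, function(h) h$name, character(1))
  expect_true("carboxylic acid" %in% nms)
  expect_false("ketone" %in% nms)
  # Boc carbamate beats the smaller amide and ester patterns on its atoms
  hits <- detect_functional_groups(mol_of("CC(C)(C)OC(=O)NCc1ccccc1"), defs)
  nms <- vapply(hits, function(h) h$name, character(1))
  expect_true("carbamate" %in% nms)
  expect_false(any(c("amide", "carboxylic ester") %in% nms))
  expect_length(detect_functional_groups(mol_of("CCCCCC"), defs), 0L)
})

test_that("group atom sets are pairwise disjoint on varied molecules", {
  defs <- fx_fgdefs()
  mols <- lapply(c("CC(C)(C)OC(=O)N(CCO)Cc1ccc(S(N)(=O)=O)cc1",
                   "O=[N+]([O-])c1ccc(C(=O)OCC#C)cc1",
                   "NC(=O)c1cnc(N2CCN(C)CC2)nc1Oc1ccccc1F",
                   "CC(=O)OC1CCC2(C)C(=CC3OC3C2O)C1"), mol_of)
  for (mol in mols) {
    hits <- detect_functional_groups(mol, defs)
    atoms <- unlist(lapply(hits, function(h) h$atoms))
    expect_false(any(duplicated(atoms)))
  }
})

test_that("ring cleanup keeps terminal heteroatoms and exocyclic doubles", {
  cases <- list(
    c("Oc1ccccc1CC", "Oc1ccccc1"),            # phenol oxygen kept
    c("c1ccc2ccccc2c1", "c1ccc2ccccc2c1"),    # naphthalene is one system
    c("O=C1CCCCC1", "O=C1CCCCC1"),            # carbonyl kept via exo double
    c("Clc1ccccc1", "c1ccccc1"),              # halogens removed
    c("Cc1ccccc1", "c1ccccc1")                # carbon side chains removed
  )
  for (cs in cases) {
    sys <- extract_ring_systems(mol_of(cs[[1]]))
    expect_length(sys, 1L)
    expect_identical(sys[[1]]$canonical_smiles, cs[[2]], info = cs[[1]])
  }
  # spiro centers join their rings into one system
  sys <- extract_ring_systems(mol_of("C1CCC2(CC1)CCCC2"))
  expect_length(sys, 1L)
})

test_that("ring systems are closed-shell and partition the ring atoms", {
  smis <- c("Oc1ccc2ccccc2c1CC1CC1", "O=C1CCC2(CC1)OCCO2",
            "c1ccc(-c2nc3ccccc3s2)cc1", "CC(=O)N1CCN(c2ccccn2)CC1")
  for (s in smis) {
    mol <- mol_of(s)
    sys <- extract_ring_systems(mol)
    # closed-shell: every emitted SMILES re-parses cleanly
    for (rs in sys) {
      expect_no_error(parse_reaction(paste0(rs$canonical_smiles, ">>",
                                            rs$canonical_smiles)))
    }
    ring_atoms <- sort(unique(unlist(mol$rings)))
    membership <- lapply(sys, function(rs)
      intersect(rs$member_atoms, ring_atoms))
    expect_identical(sort(unlist(membership)), ring_atoms, info = s)
    expect_false(any(duplicated(unlist(membership))), info = s)
  }
})

test_that("formed rings appear only for genuinely new ring systems", {
  expect_equal(nrow(formed_rings(fx_rxn("suzuki_mapped"))), 0L)
  fr <- formed_rings(fx_rxn("benzothiazole"))
  expect_equal(nrow(fr), 1L)
  expect_identical(fr$canonical_smiles, "c1ccc2scnc2c1")
  expect_equal(nrow(formed_rings(fx_rxn("identity_mapped"))), 0L)
  # substituent changes alone never create a formed ring
  expect_equal(nrow(formed_rings(fx_rxn("bromination"))), 0L)
})

test_that("Murcko scaffolds prune to rings and linkers, idempotently", {
  expect_identical(bemis_murcko_scaffold(mol_of("Cc1ccccc1"))$scaffold_smiles,
                   "c1ccccc1")
  dpm <- bemis_murcko_scaffold(mol_of("c1ccccc1Cc1ccccc1"))
  expect_identical(dpm$scaffold_smiles, "c1ccc(Cc2ccccc2)cc1")
  hex <- bemis_murcko_scaffold(mol_of("CCCCCC"))
  expect_true(hex$is_acyclic_product)
  expect_identical(hex$scaffold_smiles, "")
  for (s in c("Cc1ccc(CN2CCOCC2)cc1", "O=C(O)c1ccc2[nH]ccc2c1",
              "CC(=O)OC1CCC(c2ccncc2)CC1")) {
    sc1 <- bemis_murcko_scaffold(mol_of(s))$scaffold_smiles
    sc2 <- bemis_murcko_scaffold(mol_of(sc1))$scaffold_smiles
    expect_identical(sc2, sc1, info = s)
  }
})

test_that("scaffold pruning agrees with a brute-force terminal-pruning
           oracle on atom counts", {
  # oracle: (1) iteratively delete non-ring atoms of degree <= 1 to obtain
  # the ring+linker skeleton, then (2) restore atoms multiply bonded to a
  # skeleton atom (exocyclic =O and the like); scaffold atom count must
  # match
  prune_count <- function(mol) {
    alive <- rep(TRUE, nrow(mol$atoms))
    ring <- unique(unlist(mol$rings))
    if (!length(ring)) return(0L)
    b <- mol$bonds
    repeat {
      deg <- vapply(seq_along(alive), function(i) {
        if (!alive[i]) return(999L)
        sum((b$i == i & alive[b$j]) | (b$j == i & alive[b$i]))
      }, integer(1))
      drop <- which(alive & deg <= 1L & !(seq_along(alive) %in% ring))
      if (!length(drop)) break
      alive[drop] <- FALSE
    }
    readd <- which(!alive & vapply(seq_along(alive), function(i) {
      any((b$i == i & alive[b$j] & b$order2 >= 4) |
            (b$j == i & alive[b$i] & b$order2 >= 4))
    }, logical(1)))
    alive[readd] <- TRUE
    sum(alive)
  }
  for (s in c("Cc1ccccc1", "c1ccccc1Cc1ccccc1", "CCOC(=O)C1CCN(C)CC1",
              "O=C(NCc1ccccc1)c1ccco1")) {
    mol <- mol_of(s)
    sc <- bemis_murcko_scaffold(mol)$scaffold_smiles
    scm <- mol_of(sc)
    expect_identical(nrow(scm$atoms), prune_count(mol), info = s)
  }
})

test_that("participation is the intersection rule on T plus attached rings", {
  rxn <- fx_rxn("suzuki_mapped")
  a <- analyze(rxn, motifs = fx_motifs(), fg_defs = fx_fgdefs())
  expect_setequal(a$rings_in_center, c("c1ccccc1", "c1ccncc1"))
  s <- analyze(fx_rxn("scheme1"), motifs = fx_motifs(),
               fg_defs = fx_fgdefs())
  expect_true(all(c("aldehyde", "carboxylic acid") %in% s$groups_in_center))
  expect_identical(s$rings_in_center, "c1ccccc1")
  ident <- analyze(fx_rxn("identity_mapped"), motifs = fx_motifs(),
                   fg_defs = fx_fgdefs())
  expect_length(ident$groups_in_center, 0L)
  expect_length(ident$rings_in_center, 0L)
})
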