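# Shared fixtures: hand-mapped reactions covering all ten classes, parsed
# once per test run and cached. The transformation-matrix oracle below is
# deliberately independent of the package's matrix code: it recomputes bond
# orders and free electrons straight from the molecule graphs.

FIXTURE_SMILES <- c(
  scheme1 = paste0(
    "[O:1]=[CH:2][c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1>>",
    "[O:1]=[C:2]([OH:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1"),
  suzuki_mapped = paste0(
    "[Br:20][c:1]1[cH:2][cH:3][cH:4][cH:5][n:6]1.",
    "[OH:21][B:22]([OH:23])[c:7]1[cH:8][cH:9][c:10]([CH:11]=[O:12])",
    "[cH:13][cH:14]1>>",
    "[O:12]=[CH:11][c:10]1[cH:9][cH:8][c:7](-[c:1]2[cH:2][cH:3][cH:4]",
    "[cH:5][n:6]2)[cH:13][cH:14]1"),
  suzuki_unmapped =
    "Brc1ccccn1.O=Cc1ccc(B(O)O)cc1>>O=Cc1ccc(-c2ccccn2)cc1",
  heck = paste0(
    "[I:20][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1.",
    "[CH2:7]=[CH:8][C:9](=[O:10])[O:11][CH3:12]>>",
    "[CH3:12][O:11][C:9](=[O:10])[CH:8]=[CH:7][c:1]1[cH:2][cH:3][cH:4]",
    "[cH:5][cH:6]1"),
  amide = paste0(
    "[C:1](=[O:2])([OH:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1.",
    "[NH2:10][CH3:11]>>",
    "[C:1](=[O:2])([NH:10][CH3:11])[c:4]1[cH:5][cH:6][cH:7][cH:8]",
    "[cH:9]1.[OH2:3]"),
  boc_protection = paste0(
    "[NH2:1][CH2:2][c:3]1[cH:4][cH:5][cH:6][cH:7][cH:8]1.",
    "[CH3:9][C:10]([CH3:11])([CH3:12])[O:13][C:14](=[O:15])[O:16]",
    "[C:17](=[O:18])[O:19][C:20]([CH3:21])([CH3:22])[CH3:23]>>",
    "[C:14](=[O:15])([O:13][C:10]([CH3:9])([CH3:11])[CH3:12])[NH:1]",
    "[CH2:2][c:3]1[cH:4][cH:5][cH:6][cH:7][cH:8]1.",
    "[OH:16][C:17](=[O:18])[O:19][C:20]([CH3:21])([CH3:22])[CH3:23]"),
  boc_deprotection = paste0(
    "[C:14](=[O:15])([O:13][C:10]([CH3:9])([CH3:11])[CH3:12])[NH:1]",
    "[CH2:2][c:3]1[cH:4][cH:5][cH:6][cH:7][cH:8]1>>",
    "[NH2:1][CH2:2][c:3]1[cH:4][cH:5][cH:6][cH:7][cH:8]1"),
  friedel_crafts = paste0(
    "[CH3:1][C:2](=[O:3])[Cl:4].[cH:5]1[cH:6][cH:7][cH:8][cH:9]",
    "[cH:10]1>>",
    "[CH3:1][C:2](=[O:3])[c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1"),
  williamson = paste0(
    "[CH3:1][CH2:2][Br:3].[OH:4][c:5]1[cH:6][cH:7][cH:8][cH:9]",
    "[cH:10]1>>",
    "[CH3:1][CH2:2][O:4][c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1.",
    "[BrH:3]"),
  nitro_reduction = paste0(
    "[O:1]=[N+:2]([O-:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1>>",
    "[NH2:2][c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1.[OH2:1].[OH2:3]"),
  alcohol_oxidation = "[OH:1][CH2:2][CH2:3][CH3:4]>>[O:1]=[CH:2][CH2:3][CH3:4]",
  bromination = paste0(
    "[cH:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1>>",
    "[Br:7][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1"),
  fgi_bromide = paste0(
    "[OH:1][CH2:2][CH2:3][CH3:4].[BrH:5]>>",
    "[Br:5][CH2:2][CH2:3][CH3:4].[OH2:1]"),
  benzothiazole = paste0(
    "[NH2:1][c:2]1[cH:3][cH:4][cH:5][cH:6][c:7]1[SH:8].",
    "[O:9]=[CH:10][c:11]1[cH:12][cH:13][cH:14][cH:15][cH:16]1>>",
    "[c:10]1([c:11]2[cH:12][cH:13][cH:14][cH:15][cH:16]2)[s:8][c:7]3",
    "[cH:6][cH:5][cH:4][cH:3][c:2]3[n:1]1.[OH2:9]"),
  esterification = paste0(
    "[C:1](=[O:2])([OH:3])[CH3:4].[OH:5][CH3:6]>>",
    "[C:1](=[O:2])([O:5][CH3:6])[CH3:4].[OH2:3]"),
  tosylation = paste0(
    "[OH:1][CH2:2][CH2:3][CH3:4].ClS(=O)(=O)c1ccc(C)cc1>>",
    "[CH3:4][CH2:3][CH2:2][O:1][S:5](=[O:6])(=[O:7])[c:8]1[cH:9]",
    "[cH:10][c:11]([CH3:12])[cH:13][cH:14]1"),
  identity_mapped = "[CH3:1][CH3:2]>>[CH3:1][CH3:2]"
)

.fx_env <- new.env(parent = emptyenv())

fx_rxn <- function(name) {
  if (is.null(.fx_env$rxns)) {
    .fx_env$rxns <- parse_reactions(unname(FIXTURE_SMILES))
    names(.fx_env$rxns) <- names(FIXTURE_SMILES)
  }
  .fx_env$rxns[[name]]
}

fx_motifs <- function() {
  if (is.null(.fx_env$motifs)) .fx_env$motifs <- load_motifs()
  .fx_env$motifs
}

fx_fgdefs <- function() {
  if (is.null(.fx_env$fgdefs)) .fx_env$fgdefs <- load_functional_groups()
  .fx_env$fgdefs
}

# annotated fixture database shared across test files
fx_db <- function() {
  if (is.null(.fx_env$db)) {
    path <- make_fixture_db(seed = 7L, n_per_class = 3L,
                            path = tempfile(fileext = ".csv"))
    .fx_env$db <- annotate_database(ingest_csv(path),
                                    motifs = fx_motifs(),
                                    fg_defs = fx_fgdefs())
    .fx_env$db_csv <- path
  }
  .fx_env$db
}

fx_db_csv <- function() { fx_db(); .fx_env$db_csv }

# ---- independent transformation-matrix oracle ------------------------------

ORACLE_VE <- c(B = 3, C = 4, Si = 4, N = 5, P = 5, O = 6, S = 6,
               F = 7, Cl = 7, Br = 7, I = 7, Sn = 4, Zn = 2, Mg = 2)

oracle_side_tables <- function(mols) {
  diag <- list(); bonds <- list()
  for (mol in mols) {
    a <- mol$atoms; b <- mol$bonds
    for (i in seq_len(nrow(a))) {
      if (a$map[i] <= 0L) next
      bsum <- sum(b$order2[b$i == i | b$j == i]) / 2
      fe <- ORACLE_VE[[a$element[i]]] - bsum - a$nh[i] - a$charge[i]
      fe <- floor(fe)
      diag[[as.character(a$map[i])]] <- max(fe, 0)
    }
    for (k in seq_len(nrow(b))) {
      mi <- a$map[b$i[k]]; mj <- a$map[b$j[k]]
      if (mi > 0L && mj > 0L) {
        key <- paste(min(mi, mj), max(mi, mj))
        bonds[[key]] <- b$order2[k] / 2
      }
    }
  }
  list(diag = diag, bonds = bonds)
}

# full difference matrix over the map universe, nonzero rows retained
oracle_T <- function(rxn) {
  u <- rxn$map_universe
  r <- oracle_side_tables(rxn$reactants)
  p <- oracle_side_tables(rxn$products)
  n <- length(u)
  m <- matrix(0, n, n, dimnames = list(u, u))
  g <- function(tab, key) if (is.null(tab[[key]])) 0 else tab[[key]]
  for (i in seq_len(n)) {
    m[i, i] <- g(p$diag, as.character(u[i])) - g(r$diag, as.character(u[i]))
    for (j in seq_len(n)) {
      if (i < j) {
        key <- paste(u[i], u[j])
        d <- g(p$bonds, key) - g(r$bonds, key)
        m[i, j] <- d; m[j, i] <- d
      }
    }
  }
  keep <- which(rowSums(m != 0) > 0 | colSums(m != 0) > 0)
  list(atoms = u[keep], entries = m[keep, keep, drop = FALSE])
}

# ---- randomized variants ----------------------------------------------------

# bijective atom-map relabeling of a mapped reaction SMILES
relabel_maps <- function(rsmiles, seed) {
  maps <- unique(unlist(regmatches(
    rsmiles, gregexpr(":[0-9]+\\]", rsmiles))))
  old <- as.integer(sub("\\]", "", sub(":", "", maps)))
  set.seed(seed)
  new <- sample(seq_len(max(old) + 50L), length(old))
  out <- rsmiles
  # two-phase replacement to avoid collisions
  for (k in seq_along(old)) {
    out <- gsub(sprintf(":%d]", old[k]), sprintf(":x%d]", k), out,
                fixed = TRUE)
  }
  for (k in seq_along(old)) {
    out <- gsub(sprintf(":x%d]", k), sprintf(":%d]", new[k]), out,
                fixed = TRUE)
  }
  list(rsmiles = out, perm = stats::setNames(new, old))
}

# permute reactant molecule order
permute_reactants <- function(rsmiles, seed) {
  parts <- strsplit(rsmiles, ">", fixed = TRUE)[[1]]
  mols <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
  set.seed(seed)
  paste0(paste(sample(mols), collapse = "."), ">", parts[2], ">", parts[3])
}

# a deterministic pool of n decorated fixture reactions (relabelled and
# reactant-permuted variants of the generator families)
random_fixture_pool <- function(n, seed = 1L) {
  base <- unname(FIXTURE_SMILES[setdiff(names(FIXTURE_SMILES),
                                        c("suzuki_unmapped",
                                          "identity_mapped",
                                          "tosylation"))])
  path <- make_fixture_db(seed = seed, n_per_class = 4L,
                          path = tempfile(fileext = ".csv"))
  gen <- utils::read.csv(path, stringsAsFactors = FALSE)$rsmiles
  pool <- unique(c(base, gen))
  out <- character(n)
  for (k in seq_len(n)) {
    s <- pool[(k - 1L) %% length(pool) + 1L]
    s <- permute_reactants(s, seed + 2L * k)
    out[k] <- relabel_maps(s, seed + 2L * k + 1L)$rsmiles
  }
  out
}
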