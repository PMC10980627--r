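# Synthetic fixture reactions: hand-mapped, balanced (or deliberately
# unbalanced in the patent-literature style for deprotections) template
# reactions for each of the ten classes, decorated with ring substituents or
# chain variants that never touch the reaction center. Every generated
# reaction carries its ground-truth class and name, plus plausible condition
# strings whose per-family majorities are fixed by construction.

# substituent tokens for a generic aryl position `pos` (extra atoms use map
# numbers >= 40 so they never collide with the template skeleton)
sub_token <- function(kind, pos) {
  switch(kind,
    H = sprintf("[cH:%d]", pos),
    Me = sprintf("[c:%d]([CH3:40])", pos),
    OMe = sprintf("[c:%d]([O:40][CH3:41])", pos),
    F = sprintf("[c:%d]([F:40])", pos),
    Cl = sprintf("[c:%d]([Cl:40])", pos),
    CN = sprintf("[c:%d]([C:40]#[N:41])", pos),
    NO2 = sprintf("[c:%d]([N+:40](=[O:41])[O-:42])", pos),
    Ac = sprintf("[c:%d]([C:40](=[O:41])[CH3:42])", pos),
    n = sprintf("[n:%d]", pos),
    stop("unknown substituent: ", kind))
}

# alkyl chain variants (maps 3..6)
chain_token <- function(kind) {
  switch(kind,
    ethyl = "[CH2:3][CH3:4]",
    propyl = "[CH2:3][CH2:4][CH3:5]",
    isobutyl = "[CH2:3][CH:4]([CH3:5])[CH3:6]",
    stop("unknown chain: ", kind))
}

BOC2O <- paste0("[CH3:9][C:10]([CH3:11])([CH3:12])[O:13][C:14](=[O:15])",
                "[O:16][C:17](=[O:18])[O:19][C:20]([CH3:21])([CH3:22])",
                "[CH3:23]")
BOCOH <- "[OH:16][C:17](=[O:18])[O:19][C:20]([CH3:21])([CH3:22])[CH3:23]"

fixture_families <- function() {
  list(
    aromatic_heterocycle = list(
      class = "Aromatic Heterocycle Formation",
      name = "benzothiazole formation from aldehyde",
      variants = c("H", "Me", "n", "OMe", "F"),
      build = function(v) {
        s <- sub_token(v, 14L)
        paste0(
          "[NH2:1][c:2]1[cH:3][cH:4][cH:5][cH:6][c:7]1[SH:8].",
          "[O:9]=[CH:10][c:11]1[cH:12][cH:13]", s, "[cH:15][cH:16]1>>",
          "[c:10]1([c:11]2[cH:12][cH:13]", s, "[cH:15][cH:16]2)[s:8]",
          "[c:7]3[cH:6][cH:5][cH:4][cH:3][c:2]3[n:1]1.[OH2:9]")
      },
      solvent = c("DMSO", "ethanol"), catalyst = c(NA, NA),
      reagent = c("sodium metabisulfite", "oxygen")),
    acylation = list(
      class = "Acylation",
      name = "amide coupling with carboxylic acid",
      variants = c("H", "Me", "OMe", "F", "Cl"),
      build = function(v) {
        s <- sub_token(v, 7L)
        paste0(
          "[C:1](=[O:2])([OH:3])[c:4]1[cH:5][cH:6]", s, "[cH:8][cH:9]1.",
          "[NH2:10][CH3:11]>>",
          "[C:1](=[O:2])([NH:10][CH3:11])[c:4]1[cH:5][cH:6]", s,
          "[cH:8][cH:9]1.[OH2:3]")
      },
      solvent = c("DMF", "DCM"), catalyst = c(NA, NA),
      reagent = c("HATU;DIPEA", "EDC;HOBt")),
    fgi = list(
      class = "Functional Group Interconversion",
      name = "alcohol to alkyl bromide",
      variants = c("ethyl", "propyl", "isobutyl"),
      build = function(v) {
        ch <- chain_token(v)
        paste0("[OH:1][CH2:2]", ch, ".[BrH:30]>>",
               "[Br:30][CH2:2]", ch, ".[OH2:1]")
      },
      solvent = c("water", "toluene"), catalyst = c(NA, NA),
      reagent = c("hydrobromic acid", "sulfuric acid")),
    reduction = list(
      class = "Reduction",
      name = "nitro reduction to amine",
      variants = c("H", "Me", "OMe", "F", "Cl"),
      build = function(v) {
        s <- sub_token(v, 7L)
        paste0(
          "[O:1]=[N+:2]([O-:3])[c:4]1[cH:5][cH:6]", s, "[cH:8][cH:9]1>>",
          "[NH2:2][c:4]1[cH:5][cH:6]", s, "[cH:8][cH:9]1.",
          "[OH2:1].[OH2:3]")
      },
      solvent = c("EtOH", "MeOH"), catalyst = c("Pd/C", "Raney nickel"),
      reagent = c("hydrogen", "ammonium formate")),
    oxidation = list(
      class = "Oxidation",
      name = "oxidation of primary alcohol to aldehyde",
      variants = c("ethyl", "propyl", "isobutyl"),
      build = function(v) {
        ch <- chain_token(v)
        paste0("[OH:1][CH2:2]", ch, ">>[O:1]=[CH:2]", ch)
      },
      solvent = c("DCM", "MeCN"), catalyst = c("TEMPO", NA),
      reagent = c("Dess-Martin periodinane", "sodium hypochlorite")),
    fga = list(
      class = "Functional Group Addition",
      name = "aromatic bromination",
      variants = c("H", "Me", "OMe"),
      build = function(v) {
        s <- sub_token(v, 4L)
        paste0("[cH:1]1[cH:2][cH:3]", s, "[cH:5][cH:6]1>>",
               "[Br:30][c:1]1[cH:2][cH:3]", s, "[cH:5][cH:6]1")
      },
      solvent = c("DCM", "acetic acid"), catalyst = c(NA, "iron"),
      reagent = c("bromine", "N-bromosuccinimide")),
    cc_coupling = list(
      class = "C-C Coupling",
      name = NA_character_,  # per-variant: Suzuki or Heck
      variants = c("suzuki_H", "heck_H", "suzuki_Me", "heck_Me",
                   "suzuki_OMe", "heck_OMe", "suzuki_F", "heck_F"),
      build = function(v) {
        parts <- strsplit(v, "_", fixed = TRUE)[[1L]]
        if (parts[1L] == "suzuki") {
          s <- sub_token(parts[2L], 10L)
          paste0(
            "[Br:20][c:1]1[cH:2][cH:3][cH:4][cH:5][n:6]1.",
            "[OH:21][B:22]([OH:23])[c:7]1[cH:8][cH:9]", s,
            "[cH:13][cH:14]1>>",
            "[c:7]1([c:1]2[cH:2][cH:3][cH:4][cH:5][n:6]2)[cH:8][cH:9]",
            s, "[cH:13][cH:14]1")
        } else {
          s <- sub_token(parts[2L], 4L)
          paste0(
            "[I:30][c:1]1[cH:2][cH:3]", s, "[cH:5][cH:6]1.",
            "[CH2:7]=[CH:8][C:9](=[O:10])[O:11][CH3:12]>>",
            "[CH3:12][O:11][C:9](=[O:10])[CH:8]=[CH:7][c:1]1[cH:2]",
            "[cH:3]", s, "[cH:5][cH:6]1")
        }
      },
      name_of = function(v) {
        if (startsWith(v, "suzuki")) "Suzuki coupling with boronic acid"
        else "terminal Heck vinylation with aromatic halide"
      },
      solvent = c("DMF", "MeCN", "water"),
      catalyst = c("Pd(OAc)2", "Pd2(dba)3"),
      reagent = c("triethylamine;triphenylphosphine", "potassium carbonate")),
    heteroatom_alkylation = list(
      class = "Heteroatom Alkylation and Arylation",
      name = "Williamson ether synthesis",
      variants = c("H", "Me", "OMe", "F"),
      build = function(v) {
        s <- sub_token(v, 5L)
        paste0(
          "[OH:1][c:2]1[cH:3][cH:4]", s, "[cH:6][cH:7]1.",
          "[CH3:10][CH2:11][Br:12]>>",
          "[CH3:10][CH2:11][O:1][c:2]1[cH:3][cH:4]", s, "[cH:6][cH:7]1.",
          "[BrH:12]")
      },
      solvent = c("acetone", "DMF"), catalyst = c(NA, NA),
      reagent = c("potassium carbonate", "sodium hydride")),
    protection = list(
      class = "Protection",
      name = "Boc protection of amine",
      variants = c("H", "Me", "OMe", "F"),
      build = function(v) {
        s <- sub_token(v, 6L)
        amine_r <- paste0("[NH2:1][CH2:2][c:3]1[cH:4][cH:5]", s,
                          "[cH:7][cH:8]1")
        amine_p <- paste0("[NH:1]([CH2:2][c:3]1[cH:4][cH:5]", s,
                          "[cH:7][cH:8]1)")
        paste0(amine_r, ".", BOC2O, ">>",
               "[C:14](=[O:15])([O:13][C:10]([CH3:9])([CH3:11])[CH3:12])",
               amine_p, ".", BOCOH)
      },
      solvent = c("THF", "DCM"), catalyst = c("DMAP", NA),
      reagent = c("triethylamine", "sodium hydroxide")),
    deprotection = list(
      class = "Deprotection",
      name = "Boc deprotection",
      variants = c("H", "Me", "OMe", "F"),
      build = function(v) {
        s <- sub_token(v, 6L)
        paste0(
          "[C:14](=[O:15])([O:13][C:10]([CH3:9])([CH3:11])[CH3:12])",
          "[NH:1]([CH2:2][c:3]1[cH:4][cH:5]", s, "[cH:7][cH:8]1)>>",
          "[NH2:1][CH2:2][c:3]1[cH:4][cH:5]", s, "[cH:7][cH:8]1")
      },
      solvent = c("DCM", "dioxane"), catalyst = c(NA, NA),
      reagent = c("trifluoroacetic acid", "hydrochloric acid"))
  )
}

# cycle with the majority item in positions 1-3 and 5 so that any subset of
# size >= 1 has a strict majority of the first element
cond_at <- function(values, i) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_character_)
  if (length(values) == 1L) return(values)
  pick <- c(1L, 1L, 1L, 2L, 1L)[(i - 1L) %% 5L + 1L]
  if (pick > length(values)) pick <- 1L
  values[pick]
}

#' Generate a deterministic fixture reaction database
#'
#' Enumerates hand-mapped, substituent-decorated template reactions for each
#' of the ten reaction classes (Suzuki and Heck couplings, Williamson ether
#' synthesis, amide coupling, Boc protection and deprotection, nitro
#' reduction, alcohol oxidation, aromatic bromination, benzothiazole
#' formation, alcohol-to-bromide interconversion), with plausible condition
#' strings whose per-family majorities are fixed, and ground-truth class and
#' name labels alongside. Identical seed and size always produce an
#' identical file.
#'
#' @param seed integer seed (drives yields only; the enumeration is fixed).
#' @param n_per_class reactions per class (>= 1).
#' @param path output CSV path.
#' @return the CSV path, invisibly a data.frame attribute-free.
#' @export
make_fixture_db <- function(seed = 7L, n_per_class = 3L,
                            path = tempfile(fileext = ".csv")) {
  stopifnot(n_per_class >= 1L)
  set.seed(as.integer(seed))
  fams <- fixture_families()
  rows <- list()
  for (fam_name in names(fams)) {
    fam <- fams[[fam_name]]
    for (i in seq_len(n_per_class)) {
      v <- fam$variants[(i - 1L) %% length(fam$variants) + 1L]
      nm <- if (!is.null(fam$name_of)) fam$name_of(v) else fam$name
      rows[[length(rows) + 1L]] <- data.frame(
        rsmiles = fam$build(v),
        solvent = cond_at(fam$solvent, i),
        catalyst = cond_at(fam$catalyst, i),
        reagent = cond_at(fam$reagent, i),
        yield = round(stats::runif(1, 50, 99), 1),
        reference = sprintf("synthetic-fixture-%s-%d", fam_name, i),
        true_class = fam$class,
        true_name = nm,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' The nine Heck cross-coupling query variants
#'
#' Substituted iodo- and bromobenzenes reacting with methyl acrylate:
#' a classic condition-suggestion case study. All nine map to the same
#' precedent subset (same class, name, participating groups and rings), so
#' they must all receive the identical condition suggestion.
#'
#' @return character vector of nine mapped Reaction SMILES.
#' @export
make_heck_queries <- function() {
  combos <- list(
    c("I", "H", 4L), c("I", "NO2", 2L), c("I", "NO2", 3L),
    c("I", "Ac", 2L), c("I", "Ac", 4L), c("Br", "Cl", 4L),
    c("Br", "CN", 4L), c("Br", "H", 4L), c("Br", "Ac", 4L))
  vapply(combos, function(co) {
    x <- co[[1L]]; subk <- co[[2L]]; pos <- as.integer(co[[3L]])
    ring <- vapply(2:6, function(p) {
      if (p == pos && subk != "H") sub_token(subk, p) else
        sprintf("[cH:%d]", p)
    }, character(1))
    ring_r <- paste0("[c:1]1", paste(ring, collapse = ""), "1")
    paste0("[", x, ":30]", ring_r, ".",
           "[CH2:7]=[CH:8][C:9](=[O:10])[O:11][CH3:12]>>",
           "[CH3:12][O:11][C:9](=[O:10])[CH:8]=[CH:7]", ring_r)
  }, character(1))
}
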