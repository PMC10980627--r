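# rxnscout

Rule-based analysis of chemical reactions from Reaction SMILES: matrix
representation of the reaction center, classification into ten
medicinal-chemistry reaction classes, named-reaction recognition,
functional-group / ring / scaffold decomposition, fingerprint similarity
search, and literature-frequency suggestion of solvent, catalyst and
reagent.

**Who it is for.** Synthetic and medicinal chemists (and the tools built
for them) who want to screen a reaction database the way a chemist screens
the literature: find precedents of the same class with the same reacting
functional groups and rings, and read the conditions off the most similar
ones — without training a model.

## The method

An atom-mapped reaction over the union of map numbers (N heavy atoms) is
represented by two symmetric N×N bond-electron matrices, `M_R` (reactants)
and `M_P` (products): bond orders off the diagonal (aromatic = 1.5), free
unshared valence electrons on the diagonal. The difference

```
R = M_P − M_R
```

captures every bond and electron change; stripping all-zero rows/columns
gives the transformation matrix `T`, whose atoms are the reaction center.
An ordered cascade of ten rules on `T` (aromatic heterocycle formation,
acylation, functional group interconversion, reduction, oxidation,
functional group addition, C–C coupling, heteroatom alkylation/arylation,
protection, deprotection — first match wins, otherwise Miscellaneous)
classifies the reaction. Independently, a curated SMIRKS motif library
names it by forward template application, a 107-pattern SMARTS table
extracts functional groups, cleaned ring systems and Bemis–Murcko
scaffolds are computed, and MACCS/ECFP4 reaction fingerprints rank
precedents by Tanimoto similarity inside class/name/group/ring-keyed
subsets of an annotated database. See the methods vignette
(`vignettes/bond-electron-reaction-analysis.Rmd`) for the full rules and
their exceptions.

Chemistry primitives (SMILES/SMARTS/SMIRKS parsing, canonicalization,
fingerprints, scaffolds) are delegated to RDKit through a bundled Python
worker (`inst/python/chembridge.py`), invoked in batches; all the matrix
algebra, classification and retrieval logic is R.

## A worked example

The unbalanced oxidation of benzaldehyde to benzoic acid, atom-mapped so
that the incoming hydroxyl oxygen is map 3:

```r
library(rxnscout)
rxn <- parse_reaction(paste0(
  "[O:1]=[CH:2][c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1>>",
  "[O:1]=[C:2]([OH:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1"))
transformation_matrix(rxn)
#> <rxn_transformation> center atoms: 2, 3
#>   2 3
#> 2 0 1
#> 3 1 4
```

The stripped 2×2 matrix says: a new single bond between carbon 2 and
oxygen 3 (+1 off-diagonal), and oxygen 3 arrives carrying 4 free valence
electrons that the reactants never had (+4 diagonal) — the signature of an
oxidation. The full analysis:

```r
analyze(reaction_smiles(rxn))
#> <rxn_analysis>
#>   class:   Oxidation [oxidation]
#>   name:    oxidation of aldehyde to carboxylic acid
#>   groups in center: aldehyde, carboxylic acid
#>   rings in center:  c1ccccc1
#>   rings formed:     (none)
#>   scaffold: c1ccccc1
#>   center:   [O:1]=[CH:2][c:4]1...>>[O:1]=[C:2]([OH:3])[c:4]1...
```

Condition suggestion over a database works the same way at scale. On the
bundled synthetic fixture database, the nine classic Heck coupling
variants (substituted iodo-/bromobenzenes + methyl acrylate) all map to
one precedent subset and receive one identical suggestion:

```r
db  <- annotate_database(ingest_csv(make_fixture_db(seed = 7, n_per_class = 8)))
q   <- analyze(make_heck_queries()[1])
suggest_conditions(db, q, mode = "tight")
#> <rxn_conditions> subset of 4 precedents ( tight mode )
#>   solvents:   DMF 3 (75%),  MeCN 1 (25%)
#>   catalysts:  Pd(OAc)2 3 (75%),  Pd2(dba)3 1 (25%)
#>   reagents:   Et3N 3 (75%),  PPh3 3 (75%),  K2CO3 1 (25%)
```

A thin command-line wrapper ships in `inst/cli/rxnscout`
(`analyze`, `classify`, `name`, `fixtures`, `build-db`, `search`,
`suggest`; JSON to stdout).

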