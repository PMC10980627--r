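---
title: "Bond-electron matrices for reaction classification, naming, and condition suggestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-electron matrices for reaction classification, naming, and condition suggestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The formalism

rxnscout analyzes a chemical reaction from nothing but its Reaction SMILES.
An atom-mapped reaction over $N$ heavy atoms (the union of the atom-map
numbers on either side) is represented by two symmetric $N \times N$
bond-electron (BE) matrices in the Dugundji-Ugi tradition: $M_R$ for the
reactants and $M_P$ for the products. Off-diagonal entries $M_{ij}$ hold
the bond order between mapped atoms $i$ and $j$ (0 none, 1 single, 1.5
aromatic, 2 double, 3 triple); diagonal entries $M_{ii}$ hold the number of
free unshared valence electrons,

$$M_{ii} = (\text{group valence electrons}) - \sum_j \text{bond order}(i,j)
  - n_H(i) - \text{formal charge}(i),$$

with hydrogens counted in the bond-order sum but never given rows of their
own. The difference $R = M_P - M_R$ captures every bond-order and
free-electron change; stripping its all-zero rows and columns yields the
transformation matrix $T$, whose index set *is* the reaction center. For
the benzaldehyde-to-benzoic-acid oxidation the stripped $T$ is the
$2\times2$ block $[[0,1],[1,4]]$ over the acyl carbon and the incoming
hydroxyl oxygen: one new C-O single bond, plus an oxygen carrying four
free electrons that did not exist in the reactants.

Three bookkeeping choices matter in practice:

* **Doubled-integer storage.** All matrix entries are stored as integers
  equal to twice their chemical value (aromatic bond = 3). The
  classification rules compare exact values such as $+0.5$ and $+1.5$;
  integer storage removes floating-point comparison entirely.
  `as.matrix()` divides by two for display.
* **Unbalanced reactions are first-class.** An atom mapped on only one
  side occupies an all-zero row on the other side, which is exactly what
  makes bond cleavage to leaving groups visible in $R$. Unmapped atoms
  (spectator fragments, agents) never enter the matrices.
* **Aromatic fusion atoms.** Under the 1.5 convention a ring-fusion carbon
  sums to 4.5 bonds; the half-electron remainder is rounded down and
  clamped at zero silently. Genuinely exotic valences still warn.

Stereochemistry is stripped at parse time: enantiomers are
indistinguishable in a BE matrix, so any resolution-type reaction is
Miscellaneous by construction and stereo descriptors are never allowed to
influence a result.

## The classification cascade

A reaction is tested against ten class rules in a fixed order; the first
match wins. The order exists because the raw signatures overlap: every
bond-forming class is "a $+1$ somewhere in $T$". The rules, with the
exceptions each one carries:

1. **Aromatic heterocycle formation** - some off-diagonal $+0.5$ or $+1.5$
   *and* a product ring containing a heteroatom in which a ring bond is
   newly formed (or a ring atom has no mapped reactant counterpart). The
   ring condition is checked structurally so this rule needs no fragment
   round trip.
2. **Acylation** - a new $+1$ bond between a nitrogen or sulfur
   nucleophile and an acyl carbon (a carbon double-bonded to oxygen on
   either side). Three exceptions: O-acylations are esterifications and
   follow the Protection convention instead; carbamate formation (the new
   bond completes N-C(=O)-O) defers to Protection, so Boc-type chemistry
   is never an acylation; and a heteroatom absent from the reactants is an
   oxidative addition, not an acylation - without this the worked
   oxidation example itself would match here.
3. **Functional group interconversion** - some column of $T$ (diagonal
   included) sums to zero with only $\pm1$ entries: a bond broken and a
   bond formed at the same center. Both exchange partners must be
   non-carbon (otherwise every cross-coupling, which swaps a halide for a
   carbon, would match), and a carbon center gaining an N/O/S partner that
   already bears carbon defers to alkylation (otherwise the Williamson
   ether synthesis would be an FGI). Carbon balance required.
4. **Reduction** - no off-diagonal increases; positive diagonal entries
   are allowed only on atoms simultaneously losing bonds to oxygen (the
   deoxygenation exception, without which nitro-to-amine reduction has no
   home: the nitrogen *gains* a lone pair); remaining nonzero diagonals
   must be oxygen; a cleavage inside a protecting-group match defers to
   Deprotection (otherwise ester hydrolysis and Boc removal land here);
   carbon balance required.
5. **Oxidation** - nonnegative $T$, nonzero diagonals only oxygen, and at
   least one positive entry involving an oxygen atom; carbon balance
   required. The oxygen-involvement condition keeps oxygen-free additions
   out of this rule.
6. **Functional group addition** - nonnegative $T$ with at least one
   nonzero diagonal, all of them on heteroatoms; carbon balance required.
   Here "heteroatom" means any non-carbon element, halogens included -
   the diagonal of an unbalanced halogenation is the halogen itself. The
   at-least-one condition prevents this rule from swallowing couplings
   whose $T$ is a bare $+1$.
7. **C-C coupling** - a new bond ($M_R$ entry zero) with $+1$ between two
   carbons. Friedel-Crafts acylation lands here: no heteroatom is
   involved in its new bond.
8. **Heteroatom alkylation and arylation** - a new $+1$ bond between
   N/O/S and a non-acyl carbon.
9. **Protection** - a new $+1$ bond between a heteroatom or alkyne carbon
   and a carbon or silicon, inside a product-side match of the
   protecting-group table (carbamates, esters, silyl, benzyl, trityl,
   acetal patterns). Ester formation is deliberately routed here rather
   than to Acylation.
10. **Deprotection** - nonpositive $T$ and a fully broken bond between a
    heteroatom/alkyne carbon and carbon/silicon inside a reactant-side
    protecting-group match.

Anything else is Miscellaneous, including every reaction without a mapped
center. The bond-partner heteroatom set for rules 2, 8, 9 and 10 is
{N, O, S}; silicon is accepted only as the protecting-group partner. The
protecting-group and carbon-balance tables are data
(`inst/extdata/*.tsv`), not code, and can be replaced per call.

**Carbon balance.** The modifying classes (3-6) must conserve mapped
carbon. An imbalance is tolerated only when every surplus carbon lies
inside a match of the allowed-group table. That table ships with
sulfonyl-type fragments only (tosyl, mesyl, triflyl): adding benzyl- or
Boc-type fragments would make deprotections carbon-balanced and misroute
them into rule 4 before rule 10 can fire.

**Partial mapping.** A reaction whose product atoms are not fully mapped
is still classified on the mapped subset, but the result carries a
`low-confidence mapping` note. No mapping model is bundled;
`ensure_mapping()` accepts any user function as a provider.

## Naming

Naming is independent of mapping and of classification: a motif from the
curated SMIRKS library (65 named transformations,
`inst/extdata/reaction_motifs.tsv`) matches when its reactant templates
hit distinct reactant molecules *and* forward application of the
transformation enumerates a product whose map-free canonical SMILES equals
a recorded product. Template application was chosen over two-sided
substructure matching deliberately: substructure hits on unrelated sites
produce false positives that product-equality cannot. Priority resolves
specificity - reagent-specific motifs (methylation with methyl iodide)
outrank generic family motifs (Williamson ether synthesis) - with
alphabetical order as the deterministic tie-break. Each motif row records
an example reaction; the test suite asserts every example fires its own
motif and that an inert reaction fires none.

## Fragments, rings, scaffolds, and the center

Functional groups come from a 107-pattern SMARTS table. Each atom may
belong to at most one group: candidate matches are assigned greedily,
larger patterns first, ties broken by the fixed table order (size
descending, then name) and then by first matched atom. A group
*participates* when at least one of its atoms appears in $T$.

Ring systems merge all SSSR rings sharing atoms (naphthalene is one
system; spiro centers join their rings). Cleanup removes substituents
except terminal non-halogen *heteroatoms* bonded to a ring atom (phenol
oxygen, aniline nitrogen) and exocyclic double-bond partners (a carbonyl
oxygen on an aliphatic ring); hydrogens are then completed so every system
re-parses as a closed-shell molecule, identified by canonical SMILES. The
terminal-atom exception is restricted to heteroatoms on purpose: keeping
terminal methyls would fragment the ring vocabulary (toluene, xylenes and
benzene would all be distinct "rings") and defeat the point of ring-based
subset keys. A ring participates when one of its atoms is in $T$ or a
participating group is bonded to it; a ring is *formed* when its cleaned
canonical SMILES occurs in a product but in no reactant, so substituent
changes alone never create a formed ring.

The Bemis-Murcko scaffold of the main product (most heavy atoms, ties by
canonical SMILES) is delegated to the toolkit's Murcko implementation; the
test suite checks it against an independent iterative-pruning oracle.

The reaction center is emitted as *valid* Reaction SMILES, not as a
SMIRKS-style template: starting from the $T$ atoms plus participating
group atoms, the selection grows `radius` bond shells (default 0) and then
completes every ring system it touches, because a half-open ring is legal
in a template but a syntax error in SMILES. Selections are monotone in the
radius and saturate at the full mapped reaction.

## Similarity search and condition suggestion

Reaction fingerprints combine per-side molecular fingerprints - 166-bit
MACCS keys or 1024-bit ECFP4 (radius 2) - by concatenation (default),
union ("sum"), or as per-side bit-count differences ("difference").
Similarity is Tanimoto ($|a \wedge b| / |a \vee b|$; $\sum\min/\sum\max$
for counts; two empty vectors count as identical). Default reporting
thresholds are 0.9 for MACCS and 0.6 for ECFP4: MACCS similarities run
systematically higher than ECFP4 on the same pairs, a trend the test suite
asserts, so one shared threshold would be meaningless.

Search modes nest by construction. *Tight* keys on (class, name, sorted
participating groups, sorted participating rings), optionally narrowed by
the product scaffold; *broad* keys on (class, groups); *full* scans
everything. A database records its fingerprint configuration in a JSON
sidecar and searches refuse a mismatched query fingerprint, because a
silent scheme mismatch corrupts every similarity value.

Condition suggestion is a frequency tally over the retrieved subset:
normalized solvent/catalyst/reagent names (a small synonym table folds
"palladium(II) acetate" into "Pd(OAc)2" and the like; `;`-separated
multi-reagent fields count once per record) ranked by count with ties
alphabetical, top three by default. The suggestion depends only on the
subset, never on row order. It is a literature-frequency lookup and
nothing more - solubility and compatibility of the species are not
modelled, and the output says so.

## The synthetic fixture generator

`make_fixture_db()` defines the conditions under which the package is
tested. It enumerates hand-mapped template reactions for all ten classes -
Suzuki and Heck couplings, Williamson ether synthesis, amide coupling,
Boc protection and deprotection, nitro reduction, primary-alcohol
oxidation, aromatic bromination, benzothiazole formation, and
alcohol-to-bromide interconversion - each decorated with ring substituents
(H, methyl, methoxy, fluoro, and a pyridyl variant in the benzothiazole
family) or chain variants that never touch the reaction center. Reactions
are written fully mapped and balanced with explicit co-products (water,
HBr), except deprotections and the unbalanced bromination, which follow
the patent-literature habit of dropping the cleaved fragment or the
reagent. Condition strings cycle deterministically with the majority item
in four of every five positions, so every family has a strict majority
solvent, catalyst and reagent for any subset size; the seed drives only
the yield column. Ground-truth class and name labels are written
alongside, and the nine Heck query variants (substituted iodo- and
bromobenzenes with methyl acrylate) are available via
`make_heck_queries()`.

What the generator emulates: clean atom mapping, center-preserving
decoration, heterogeneous condition spellings, duplicate chemistry under
different maps. What it does not emulate: mapping errors from a neural
mapper, genuinely unbalanced patent records with missing reagents, agent
streams, stereochemistry, or free-text condition fields beyond the
synonym table. Passing the fixture suite therefore demonstrates the
correctness of the matrix algebra, the cascade logic and the retrieval
machinery under controlled mapping - it does not certify accuracy on
noisy mapped patent data, where mapping quality dominates.

## Problem sizes and determinism

The shipped test and demonstration workloads use fixture databases of 30
to 88 records (3 to 8 per class before deduplication), 200 randomized
map-relabelled and reactant-permuted variants for the property suites,
and the nine-query Heck case study. All randomness is seed-controlled;
every pipeline stage is deterministic given its inputs, and annotation of
a database is idempotent. Chemistry primitives (SMILES/SMARTS/SMIRKS,
canonicalization, fingerprints, Murcko scaffolds) run in a bundled RDKit
worker invoked in batches - a full database annotation costs a fixed
number of worker round trips regardless of size.

## Known limitations

* Classification quality is bounded by mapping quality; the matrices see
  only mapped atoms.
* The exception set is minimal and principled rather than exhaustive;
  borderline chemistry (tosylation, ammonia aminations, acetal formation)
  can land in a defensible but debatable class, and the cascade order is
  the final arbiter.
* The motif library covers 65 common named reactions; unnamed reactions
  are a normal outcome (`NA`), not an error.
* Charged, exotic-valence species outside the main-group table are
  rejected on the matrix diagonal rather than guessed.
* Condition suggestion inherits every bias of the underlying database.
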