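#!/usr/bin/env python
"""Batched cheminformatics worker around RDKit.

Reads one JSON object {"ops": [...]} on stdin, writes {"results": [...]} on
stdout.  Each op is processed independently; per-item failures are reported as
{"error": "..."} entries so a single bad SMILES never aborts a batch.  All
SMILES handling strips stereochemistry (enantiomer resolution is out of scope
for the matrix formalism) and all canonical output drops atom maps.
"""

import sys
import json
import itertools

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, MACCSkeys
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def strip_stereo(mol):
    Chem.RemoveStereochemistry(mol)
    return mol


def canon(mol):
    m = Chem.Mol(mol)
    Chem.RemoveStereochemistry(m)
    for a in m.GetAtoms():
        a.SetAtomMapNum(0)
    return Chem.MolToSmiles(m)


def mol_from_smiles(smi):
    m = Chem.MolFromSmiles(smi)
    if m is None:
        raise ValueError("unparsable SMILES: %s" % smi)
    return strip_stereo(m)


def describe_mol(mol):
    """Emit the molecule graph with atom order tied to the emitted SMILES.

    The reported atom indices refer to the parse order of the *emitted*
    mapped SMILES string, so any later op that re-parses that string sees an
    identical ordering.
    """
    s1 = Chem.MolToSmiles(mol)
    m2 = Chem.MolFromSmiles(s1)
    if m2 is None:  # should not happen for sanitized molecules
        raise ValueError("round-trip failure: %s" % s1)
    atoms = []
    for a in m2.GetAtoms():
        atoms.append({
            "el": a.GetSymbol(),
            "map": a.GetAtomMapNum(),
            "chg": a.GetFormalCharge(),
            "arom": bool(a.GetIsAromatic()),
            "nh": a.GetTotalNumHs(),
        })
    bonds = []
    for b in m2.GetBonds():
        bonds.append([b.GetBeginAtomIdx(), b.GetEndAtomIdx(),
                      int(round(2 * b.GetBondTypeAsDouble())),
                      bool(b.GetIsAromatic())])
    rings = [list(r) for r in m2.GetRingInfo().AtomRings()]
    return {"smiles": s1, "csmiles": canon(m2), "atoms": atoms,
            "bonds": bonds, "rings": rings}


def parse_side(segment):
    if segment == "":
        return []
    mol = Chem.MolFromSmiles(segment)
    if mol is None:
        # name the offending fragment for the diagnostic
        for frag in segment.split("."):
            if frag and Chem.MolFromSmiles(frag) is None:
                raise ValueError("unparsable SMILES fragment: %s" % frag)
        raise ValueError("unparsable SMILES segment: %s" % segment)
    strip_stereo(mol)
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    return [describe_mol(f) for f in frags]


def op_parse(op):
    out = []
    for rs in op["rsmiles"]:
        try:
            parts = rs.split(">")
            if len(parts) != 3:
                raise ValueError(
                    "reaction SMILES must contain exactly two '>' separators")
            res = {
                "reactants": parse_side(parts[0]),
                "agents": parse_side(parts[1]),
                "products": parse_side(parts[2]),
            }
            out.append(res)
        except Exception as e:
            out.append({"error": str(e)})
    return out


def op_checksmarts(op):
    out = []
    for s in op["smarts"]:
        patt = Chem.MolFromSmarts(s)
        if patt is None:
            out.append({"ok": False, "natoms": 0})
        else:
            out.append({"ok": True, "natoms": patt.GetNumAtoms()})
    return out


def op_match(op):
    patts = []
    for s in op["smarts"]:
        p = Chem.MolFromSmarts(s)
        patts.append(p)  # None allowed; reported as error below
    out = []
    for smi in op["smiles"]:
        try:
            m = mol_from_smiles(smi)
        except ValueError as e:
            out.append({"error": str(e)})
            continue
        per = []
        for p in patts:
            if p is None:
                per.append({"error": "invalid SMARTS"})
            else:
                hits = m.GetSubstructMatches(p, uniquify=True, maxMatches=500)
                per.append([list(h) for h in hits])
        out.append({"matches": per})
    return out


def extract_fragment(mol, keep, keep_maps):
    keep = set(keep)
    rw = Chem.RWMol(mol)
    lost = set()
    for b in mol.GetBonds():
        i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        if (i in keep) != (j in keep):
            lost.add(i if i in keep else j)
    for idx in sorted(set(range(mol.GetNumAtoms())) - keep, reverse=True):
        rw.RemoveAtom(idx)
    # atoms written as bracket atoms carry fixed H counts; atoms that lost a
    # neighbour must be allowed to regain implicit hydrogens
    old_new = {o: n for n, o in enumerate(sorted(keep))}
    for o in lost:
        a = rw.GetAtomWithIdx(old_new[o])
        a.SetNoImplicit(False)
    m = rw.GetMol()
    Chem.SanitizeMol(m)
    if not keep_maps:
        for a in m.GetAtoms():
            a.SetAtomMapNum(0)
    Chem.RemoveStereochemistry(m)
    return Chem.MolToSmiles(m)


def op_frag(op):
    out = []
    for job in op["jobs"]:
        try:
            m = mol_from_smiles(job["smiles"])
            out.append({"smiles": extract_fragment(
                m, job["atoms"], bool(job.get("keep_maps", False)))})
        except Exception as e:
            out.append({"error": str(e)})
    return out


def op_name(op):
    motifs = []
    for s in op["smirks"]:
        try:
            rxn = AllChem.ReactionFromSmarts(s)
            rxn.Initialize()
            motifs.append(rxn)
        except Exception:
            motifs.append(None)
    out = []
    for job in op["jobs"]:
        try:
            rmols = []
            for smi in job["reactants"]:
                # round-trip through the map-free canonical form so bracket
                # atoms lose their fixed explicit-H counts; otherwise
                # template application on mapped input fails sanitization
                m = Chem.MolFromSmiles(canon(mol_from_smiles(smi)))
                rmols.append(m)
            targets = set()
            for smi in job["products"]:
                targets.add(canon(mol_from_smiles(smi)))
            fired = []
            for k, rxn in enumerate(motifs):
                if rxn is None:
                    continue
                n = rxn.GetNumReactantTemplates()
                if n > len(rmols):
                    continue
                hit = False
                count = 0
                for combo in itertools.permutations(range(len(rmols)), n):
                    count += 1
                    if count > 120:
                        break
                    ok = True
                    for t in range(n):
                        if not rmols[combo[t]].HasSubstructMatch(
                                rxn.GetReactantTemplate(t)):
                            ok = False
                            break
                    if not ok:
                        continue
                    try:
                        psets = rxn.RunReactants(
                            tuple(rmols[c] for c in combo))
                    except Exception:
                        continue
                    for ps in psets:
                        for p in ps:
                            try:
                                Chem.SanitizeMol(p)
                            except Exception:
                                continue
                            if canon(p) in targets:
                                hit = True
                                break
                        if hit:
                            break
                    if hit:
                        break
                if hit:
                    fired.append(k)
            out.append({"fired": fired})
        except Exception as e:
            out.append({"error": str(e)})
    return out


def op_checksmirks(op):
    out = []
    for s in op["smirks"]:
        try:
            rxn = AllChem.ReactionFromSmarts(s)
            rxn.Initialize()
            out.append({"ok": True, "ntemplates": rxn.GetNumReactantTemplates()})
        except Exception:
            out.append({"ok": False, "ntemplates": 0})
    return out


def mol_bits(m, scheme):
    if scheme == "maccs":
        # bit 0 of the RDKit MACCS implementation is unused; report keys 1-166
        # as 0-based indices 0..165
        return [b - 1 for b in MACCSkeys.GenMACCSKeys(m).GetOnBits() if b >= 1]
    return list(AllChem.GetMorganFingerprintAsBitVect(
        m, 2, nBits=1024).GetOnBits())


def op_fp(op):
    scheme = op["scheme"]
    counts = bool(op.get("counts", False))
    out = []
    for mols in op["smiles_sets"]:
        try:
            acc = {}
            for smi in mols:
                m = mol_from_smiles(smi)
                for b in mol_bits(m, scheme):
                    acc[b] = acc.get(b, 0) + 1
            if counts:
                out.append({"bits": sorted(acc.keys()),
                            "counts": [acc[b] for b in sorted(acc.keys())]})
            else:
                out.append({"bits": sorted(acc.keys())})
        except Exception as e:
            out.append({"error": str(e)})
    return out


def op_murcko(op):
    out = []
    for smi in op["smiles"]:
        try:
            m = mol_from_smiles(smi)
            for a in m.GetAtoms():
                a.SetAtomMapNum(0)
            sc = MurckoScaffold.GetScaffoldForMol(m)
            out.append({"smiles": Chem.MolToSmiles(sc) if sc is not None else ""})
        except Exception as e:
            out.append({"error": str(e)})
    return out


def op_canon(op):
    out = []
    for smi in op["smiles"]:
        try:
            out.append({"smiles": canon(mol_from_smiles(smi))})
        except Exception as e:
            out.append({"error": str(e)})
    return out


HANDLERS = {
    "parse": op_parse,
    "match": op_match,
    "checksmarts": op_checksmarts,
    "checksmirks": op_checksmirks,
    "frag": op_frag,
    "name": op_name,
    "fp": op_fp,
    "murcko": op_murcko,
    "canon": op_canon,
}


def main():
    req = json.load(sys.stdin)
    results = []
    for op in req.get("ops", []):
        kind = op.get("op")
        if kind not in HANDLERS:
            results.append({"error": "unknown op: %s" % kind})
            continue
        try:
            results.append({"ok": HANDLERS[kind](op)})
        except Exception as e:
            results.append({"error": str(e)})
    json.dump({"results": results}, sys.stdout)
    sys.stdout.write("\n")


if __name__ == "__main__":
    main()
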