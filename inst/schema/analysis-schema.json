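{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "rxnscout reaction analysis",
  "type": "object",
  "required": ["reaction_smiles", "reaction_class", "matched_rule",
               "groups_in_center", "rings_in_center", "rings_formed",
               "warnings"],
  "properties": {
    "reaction_smiles": {"type": "string"},
    "reaction_class": {
      "type": "string",
      "enum": ["Aromatic Heterocycle Formation", "Acylation",
               "Functional Group Interconversion", "Reduction", "Oxidation",
               "Functional Group Addition", "C-C Coupling",
               "Heteroatom Alkylation and Arylation", "Protection",
               "Deprotection", "Miscellaneous"]
    },
    "matched_rule": {"type": "string"},
    "name": {"type": ["string", "null"]},
    "groups_in_center": {"type": "array", "items": {"type": "string"}},
    "rings_in_center": {"type": "array", "items": {"type": "string"}},
    "rings_formed": {"type": "array", "items": {"type": "string"}},
    "scaffold": {"type": ["string", "null"]},
    "center": {
      "type": ["object", "null"],
      "required": ["center_smiles", "included_atom_maps", "radius"],
      "properties": {
        "center_smiles": {"type": "string"},
        "included_atom_maps": {"type": "array", "items": {"type": "integer"}},
        "radius": {"type": "integer"}
      }
    },
    "warnings": {"type": "array", "items": {"type": "string"}}
  }
}
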