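[
  {"name": "Abz",   "site": "N_term", "formula": "C7H5NO",
   "comment": "ortho-aminobenzoyl fluorophore, acylates the N-terminal amine"},
  {"name": "EDDnp", "site": "C_term", "formula": "C8H9N4O4", "removed": "OH",
   "comment": "ethylenediamine-2,4-dinitrophenyl quencher, amidates the C-terminus"},
  {"name": "amide", "site": "C_term", "formula": "NH2", "removed": "OH"}
]
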