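[
  {
    "id": "SF 29-35",
    "sequence": "LERMFLSQ",
    "n_mod": "Abz",
    "c_mod": "EDDnp",
    "parent_offset": 29,
    "comment": "alpha-chain residues 29-35 plus the EDDnp-bearing Gln"
  },
  {
    "id": "SF 57-67",
    "sequence": "GHGAKVAAALTQQ",
    "n_mod": "Abz",
    "c_mod": "EDDnp",
    "parent_offset": 57,
    "comment": "alpha-chain residues 57-67 plus the EDDnp-bearing Gln pair"
  }
]
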