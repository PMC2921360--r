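[
  {"chain_id": "alpha", "start": 1,   "end": 29,  "name": "Hb alpha 1-29",   "source": "reported antimicrobial hemoglobin fragment"},
  {"chain_id": "alpha", "start": 1,   "end": 32,  "name": "Hb alpha 1-32",   "source": "reported antimicrobial hemoglobin fragment"},
  {"chain_id": "alpha", "start": 84,  "end": 98,  "name": "Hb alpha 84-98",  "source": "reported antimicrobial hemoglobin fragment"},
  {"chain_id": "beta",  "start": 1,   "end": 13,  "name": "Hb beta 1-13",    "source": "reported antimicrobial hemoglobin fragment"},
  {"chain_id": "alpha", "start": 133, "end": 141, "name": "Hb alpha 133-141","source": "reported antimicrobial hemoglobin fragment"},
  {"chain_id": "beta",  "start": 127, "end": 145, "name": "Hb beta 127-145", "source": "reported antimicrobial hemoglobin fragment"},
  {"chain_id": "alpha", "start": 1,   "end": 25,  "name": "Hb alpha 1-25",   "source": "reported human hemocidin"},
  {"chain_id": "alpha", "start": 1,   "end": 33,  "name": "Hb alpha 1-33",   "source": "reported human hemocidin"},
  {"chain_id": "alpha", "start": 34,  "end": 46,  "name": "Hb alpha 34-46",  "source": "reported antimicrobial hemoglobin fragment"}
]
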