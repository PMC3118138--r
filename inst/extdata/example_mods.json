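[
  {"target": "GPD1", "kind": "deletion"},
  {"target": "GPD2", "kind": "deletion"},
  {"target": "mhpF", "kind": "insertion",
   "added_reaction": {
     "id": "AALD",
     "name": "acetylating acetaldehyde dehydrogenase route (lumped)",
     "equation": "ACE_c + 2 NADH_c + 2 ATP_c + H2O_c -> ETH_c + 2 NAD_c + 2 ADP_c + 2 PI_c",
     "lb": 0, "ub": "inf"}}
]
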