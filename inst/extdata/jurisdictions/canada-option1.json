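{
  "schema_version": 1,
  "jurisdiction_id": "canada-option1",
  "name": "Canada (proposed Option 1): absolute protein per reference amount",
  "basis": "ra",
  "metric": "protein-g",
  "tiers": [
    {"tier": "good-source", "comparator": ">=", "threshold": 5,
     "citation": "Proposed harmonisation with FSANZ per-serving thresholds (5 g / 10 g), applied per Canadian reference amount"},
    {"tier": "excellent-source", "comparator": ">=", "threshold": 10,
     "citation": "Proposed harmonisation with FSANZ per-serving thresholds (5 g / 10 g), applied per Canadian reference amount"}
  ],
  "constants": {},
  "notes": "Protein quality is not considered; companion foods combine by plain summation of grams per reference amount."
}
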