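{
  "schema_version": 1,
  "jurisdiction_id": "anz",
  "name": "Australia / New Zealand: absolute protein per serving",
  "basis": "serving",
  "metric": "protein-g",
  "tiers": [
    {"tier": "general", "comparator": ">=", "threshold": 5,
     "citation": "FSANZ Food Standards Code, Standard 1.2.7 Schedule 4: protein claim, >= 5 g per serving"},
    {"tier": "good-source", "comparator": ">=", "threshold": 10,
     "citation": "FSANZ Food Standards Code, Standard 1.2.7 Schedule 4: good source, >= 10 g per serving"}
  ],
  "constants": {},
  "notes": ""
}
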