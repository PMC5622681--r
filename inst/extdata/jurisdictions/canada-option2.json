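{
  "schema_version": 1,
  "jurisdiction_id": "canada-option2",
  "name": "Canada (proposed Option 2): PDCAAS-corrected protein vs 50 g DV",
  "basis": "ra",
  "metric": "percent-dv",
  "tiers": [
    {"tier": "source", "comparator": ">=", "threshold": 5,
     "citation": "Proposed three-tier framework: 5% DV (2.5 g) floor mirrors the Canadian 'source of' threshold for vitamins, minerals and fibre"},
    {"tier": "good-source", "comparator": ">=", "threshold": 10,
     "citation": "Proposed three-tier framework: 10% DV (5 g) aligns with the USA good-source threshold"},
    {"tier": "excellent-source", "comparator": ">=", "threshold": 20,
     "citation": "Proposed three-tier framework: 20% DV (10 g) aligns with the USA excellent-source threshold"}
  ],
  "constants": {
    "dv_g": {"value": 50, "unit": "g",
      "citation": "Proposed adoption of the USA protein Daily Value of 50 g for >= 4 y through adults"}
  },
  "notes": "Metric is PDCAAS-corrected protein per reference amount as % of the 50 g DV; declared companion foods combine by summing corrected protein before taking %DV."
}
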