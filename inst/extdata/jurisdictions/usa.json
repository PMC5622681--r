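{
  "schema_version": 1,
  "jurisdiction_id": "usa",
  "name": "USA: PDCAAS-corrected protein vs DV per RACC",
  "basis": "racc",
  "metric": "percent-dv",
  "tiers": [
    {"tier": "good-source", "comparator": ">=", "threshold": 10,
     "citation": "FDA 21 CFR 101.54(b): 10-19% of the RDI or DRV per RACC"},
    {"tier": "excellent-source", "comparator": ">=", "threshold": 20,
     "citation": "FDA 21 CFR 101.54(a): >= 20% of the RDI or DRV per RACC"}
  ],
  "constants": {
    "dv_g": {"value": 50, "unit": "g",
      "citation": "FDA protein DRV, adults and children >= 4 y: 50 g"},
    "dv_g_1_3y": {"value": 13, "unit": "g",
      "citation": "FDA protein DRV, children 1 through 3 y: 13 g"}
  },
  "notes": "Foods for infants (<= 12 months) require the PER bioassay and are not evaluable here."
}
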