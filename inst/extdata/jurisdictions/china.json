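{
  "schema_version": 1,
  "jurisdiction_id": "china",
  "name": "China: percent of protein NRV",
  "basis": "nrv-routes",
  "metric": "percent-nrv",
  "tiers": [
    {"tier": "source", "comparator": ">=", "threshold_multiplier": 1,
     "citation": "China GB 28050-2011: source of protein"},
    {"tier": "high-source", "comparator": ">=", "threshold_multiplier": 2,
     "citation": "China GB 28050-2011: high in protein, 2x the source level"}
  ],
  "routes": [
    {"route": "per-100g", "applies_to": "solid", "threshold_pct_nrv": 10,
     "citation": "China GB 28050-2011: >= 10% NRV per 100 g (solids)"},
    {"route": "per-100mL", "applies_to": "liquid", "threshold_pct_nrv": 5,
     "citation": "China GB 28050-2011: >= 5% NRV per 100 mL (liquids)"},
    {"route": "per-energy", "threshold_pct_nrv": 5,
     "citation": "China GB 28050-2011: >= 5% NRV per 420 kJ"}
  ],
  "constants": {
    "nrv_g": {"value": 60, "unit": "g",
      "citation": "China protein NRV (GB 28050-2011): 60 g/day"}
  },
  "energy_rule_unit": "kJ-420",
  "notes": "No per-serving route; energy route uses 420 kJ."
}
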