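{
  "schema_version": 1,
  "jurisdiction_id": "south-korea",
  "name": "South Korea: percent of protein NRV",
  "basis": "nrv-routes",
  "metric": "percent-nrv",
  "tiers": [
    {"tier": "source", "comparator": ">=", "threshold_multiplier": 1,
     "citation": "South Korea MFDS food labelling standards: source of protein"},
    {"tier": "high-source", "comparator": ">=", "threshold_multiplier": 2,
     "citation": "South Korea MFDS food labelling standards: high in protein, 2x the source level"}
  ],
  "routes": [
    {"route": "per-100g", "applies_to": "solid", "threshold_pct_nrv": 10,
     "citation": "South Korea MFDS: >= 10% NRV per 100 g (solids)"},
    {"route": "per-100mL", "applies_to": "liquid", "threshold_pct_nrv": 5,
     "citation": "South Korea MFDS: >= 5% NRV per 100 mL (liquids)"},
    {"route": "per-energy", "threshold_pct_nrv": 5,
     "citation": "South Korea MFDS: >= 5% NRV per 100 kcal"},
    {"route": "per-serving", "threshold_pct_nrv": 10,
     "citation": "South Korea MFDS: >= 10% NRV per serving"}
  ],
  "constants": {
    "nrv_g": {"value": 55, "unit": "g",
      "citation": "South Korea protein NRV: 55 g/day"}
  },
  "energy_rule_unit": "kcal-100",
  "notes": ""
}
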