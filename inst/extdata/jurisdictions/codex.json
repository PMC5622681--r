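{
  "schema_version": 1,
  "jurisdiction_id": "codex",
  "name": "Codex Alimentarius: percent of protein NRV",
  "basis": "nrv-routes",
  "metric": "percent-nrv",
  "tiers": [
    {"tier": "source", "comparator": ">=", "threshold_multiplier": 1,
     "citation": "Codex CAC/GL 23-1997: source of protein"},
    {"tier": "high-source", "comparator": ">=", "threshold_multiplier": 2,
     "citation": "Codex CAC/GL 23-1997: high in protein, at least 2x the source level"}
  ],
  "routes": [
    {"route": "per-100g", "applies_to": "solid", "threshold_pct_nrv": 10,
     "citation": "Codex CAC/GL 23-1997: >= 10% NRV per 100 g (solids)"},
    {"route": "per-100mL", "applies_to": "liquid", "threshold_pct_nrv": 5,
     "citation": "Codex CAC/GL 23-1997: >= 5% NRV per 100 mL (liquids)"},
    {"route": "per-energy", "threshold_pct_nrv": 5,
     "citation": "Codex CAC/GL 23-1997: >= 5% NRV per 100 kcal"},
    {"route": "per-serving", "threshold_pct_nrv": 10,
     "citation": "Codex CAC/GL 23-1997: >= 10% NRV per serving"}
  ],
  "constants": {
    "nrv_g": {"value": 50, "unit": "g",
      "citation": "Codex protein NRV: 50 g/day"}
  },
  "energy_rule_unit": "kcal-100",
  "notes": "A food is a source if ANY route meets its threshold; high source if any route meets 2x its threshold."
}
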