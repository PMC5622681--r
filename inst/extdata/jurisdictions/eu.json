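{
  "schema_version": 1,
  "jurisdiction_id": "eu",
  "name": "European Union: percent of energy from protein",
  "basis": "serving",
  "metric": "percent-energy",
  "tiers": [
    {"tier": "source", "comparator": ">=", "threshold": 12,
     "citation": "EU Regulation (EC) 1924/2006, Annex: source of protein, >= 12% of energy from protein"},
    {"tier": "high-source", "comparator": ">=", "threshold": 20,
     "citation": "EU Regulation (EC) 1924/2006, Annex: high in protein, >= 20% of energy from protein"}
  ],
  "constants": {
    "protein_kcal_per_g": {"value": 4, "unit": "kcal/g",
      "citation": "Atwater general factor for protein (17 kJ/g)"}
  },
  "notes": "Metric: protein grams per serving x 4 kcal/g, over total energy per serving."
}
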