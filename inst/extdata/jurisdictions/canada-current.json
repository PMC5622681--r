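{
  "schema_version": 1,
  "jurisdiction_id": "canada-current",
  "name": "Canada (current): PER and protein rating",
  "basis": "rdi",
  "metric": "protein-rating",
  "tiers": [
    {"tier": "good-source", "comparator": ">=", "threshold": 20,
     "citation": "Canadian Food and Drug Regulations, B.01.305; CFIA Industry Labelling Tool"},
    {"tier": "excellent-source", "comparator": ">=", "threshold": 40,
     "citation": "Canadian Food and Drug Regulations, B.01.305; CFIA Industry Labelling Tool"}
  ],
  "constants": {
    "casein_per": {"value": 2.5, "unit": "dimensionless",
      "citation": "Health Canada Official Method FO-1 (1981): adjusted PER standardised to casein = 2.5"}
  },
  "notes": "Two-tier system; 'source of' and 'good source of' protein claims are treated as equivalent. When a food has no RDI, the reference amount may be used (flagged in the trace). Combination is restricted to declared pairs (breakfast cereal evaluated per 30 g combined with 125 mL milk)."
}
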