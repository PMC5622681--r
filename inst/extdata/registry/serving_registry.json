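{
  "schema_version": 1,
  "entries": [
    {
      "food_category": "high-density breakfast cereal",
      "rdi": {"amount": 28, "unit": "g",
        "note": "consumed alone; 30 g when combined with 125 mL milk"},
      "rdi_with_companion": {"amount": 30, "unit": "g"},
      "ra": {"amount": 55, "unit": "g"},
      "racc": {"amount": 55, "unit": "g"},
      "source": "Canadian Food and Drug Regulations Schedule K (RDI); Health Canada reference amounts table (RA, >= 43 g per 250 mL)"
    },
    {
      "food_category": "low-density breakfast cereal",
      "rdi_with_companion": {"amount": 30, "unit": "g"},
      "ra": {"amount": 30, "unit": "g"},
      "racc": {"amount": 40, "unit": "g"},
      "source": "Health Canada reference amounts table (20-42 g per 250 mL); FDA RACC table (20 to < 43 g per 240 mL)"
    },
    {
      "food_category": "milk",
      "rdi": {"amount": 852, "unit": "mL"},
      "rdi_with_companion": {"amount": 125, "unit": "mL",
        "note": "when consumed with breakfast cereal"},
      "ra": {"amount": 250, "unit": "mL"},
      "source": "Canadian Food and Drug Regulations Schedule K (RDI 852 mL); Health Canada reference amounts table (RA 250 mL)"
    },
    {
      "food_category": "bread",
      "rdi": {"amount": 125, "unit": "g", "note": "5 slices"},
      "ra": {"amount": 75, "unit": "g"},
      "racc": {"amount": 50, "unit": "g"},
      "source": "Canadian Food and Drug Regulations Schedule K (RDI); Health Canada reference amounts table (RA); FDA RACC table"
    },
    {
      "food_category": "pancakes",
      "ra": {"amount": 75, "unit": "g"},
      "racc": {"amount": 110, "unit": "g"},
      "source": "Health Canada reference amounts table (RA); FDA RACC table; no RDI exists, the RA is used for protein rating"
    },
    {
      "food_category": "pasta (dry)",
      "rdi": {"amount": 85, "unit": "g"},
      "ra": {"amount": 55, "unit": "g"},
      "racc": {"amount": 55, "unit": "g"},
      "source": "Canadian Food and Drug Regulations Schedule K (RDI); Health Canada reference amounts table (RA); FDA RACC table"
    }
  ]
}
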