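{
  "schema_version": 1,
  "population_label": "preschool children 2-5 y",
  "provenance": "external: transcribed from FAO/WHO (1991) Protein Quality Evaluation, Report of the Joint FAO/WHO Expert Consultation, FAO Food and Nutrition Paper 51, Rome. Values are reference data from that report, not measured here; the file is swappable.",
  "units": "mg amino acid per g protein",
  "requirement": {
    "His": 19,
    "Ile": 28,
    "Leu": 66,
    "Lys": 58,
    "Met+Cys": 25,
    "Phe+Tyr": 63,
    "Thr": 34,
    "Trp": 11,
    "Val": 35
  }
}
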