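Package: proteinclaims
Title: Protein Quality Scoring and Protein Content Claim Eligibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes protein quality scores and evaluates protein
    nutrient content claim eligibility across regulatory jurisdictions.
    Implements the Canadian protein efficiency ratio (PER) and protein
    rating method, the protein digestibility corrected amino acid score
    (PDCAAS) for single foods and multi-ingredient mixtures (1991 and
    2007 weighting variants), the PDCAAS-to-PER conversion used by the
    Canadian Food Inspection Agency, and a configurable rules engine
    covering the current Canadian framework, two proposed Canadian
    frameworks, the USA percent daily value framework, the EU
    energy-fraction rules, Australia/New Zealand per-serving thresholds,
    and the Codex/China/South Korea nutrient reference value family.
    Ships provenance-tagged reference data (scoring patterns,
    jurisdiction parameter sets, serving-basis registry), worked-example
    food fixtures, a seeded synthetic-food generator for property
    testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
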