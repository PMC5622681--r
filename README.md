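# proteinclaims

Protein quality scoring and protein content claim eligibility, for food
scientists and regulatory-affairs practitioners who need to know whether a
food qualifies for a "source of protein" (or better) claim — and under
which jurisdiction's rules.

Whether a food may carry a protein content claim depends not just on how
much protein it contains but, in Canada and the USA, on the *quality* of
that protein:

* **Canada (current).** The protein rating is PER × g protein in the
  Reasonable Daily Intake (RDI), where PER is the protein efficiency ratio
  from the rat growth bioassay, standardised so casein scores 2.5. A rating
  ≥ 20 is a good source, ≥ 40 an excellent source. Where no measured PER
  exists, the CFIA permits PER = PDCAAS × 2.5.
* **USA.** PDCAAS — the protein digestibility corrected amino acid score,
  `min_a(content_a / requirement_a) × digestibility`, truncated at 1 — is
  multiplied by g protein per reference amount customarily consumed (RACC)
  and expressed as % of the 50 g Daily Value (13 g for ages 1–3):
  ≥ 10 %DV good source, ≥ 20 %DV excellent source.
* **Proposed Canadian Option 1** drops quality entirely: ≥ 5 g / ≥ 10 g
  protein per reference amount.
* **Proposed Canadian Option 2** adopts PDCAAS with a three-tier %DV scale
  (≥ 5 / ≥ 10 / ≥ 20 %DV of 50 g).
* **EU** (≥ 12% / ≥ 20% of energy from protein), **Australia/New Zealand**
  (≥ 5 g / ≥ 10 g per serving) and the **Codex / China / South Korea** NRV
  family (≥ 10% of the protein NRV per 100 g, ≥ 5% per 100 mL or per
  100 kcal / 420 kJ, ≥ 10% per serving; double it for "high in protein")
  use absolute thresholds.

The package implements all of these as a data-driven rules engine, plus the
underlying arithmetic: amino acid scoring against a reference pattern,
single- and multi-ingredient PDCAAS (both the 1991 profile-first and the
2007 digestibility-weighted conventions), the PDCAAS→PER conversion,
protein ratings, corrected protein and %DV. Every evaluation returns the
awarded tier together with a human-readable calculation trace.

## Worked example

A high-density chickpea-based breakfast cereal (5 g protein per 55 g
reference amount, measured PER 2.32, PDCAAS 0.52) evaluated with 125 mL of
2% milk (4.3 g protein, PER 2.5, PDCAAS 1.0):

```r
library(proteinclaims)
wx <- worked_examples()
evaluate_canada_current(wx$foods$chickpea_cereal, wx$foods$milk_125,
                        paper_rounding = TRUE)
#> [canada-current] tier: none  (metric 17.100 on rdi, threshold -)
#>     chickpea-based breakfast cereal: combined-consumption RDI 30 used
#>     chickpea-based breakfast cereal: PER 2.32 (measured) x 2.7 g protein per 30 = rating 6.3
#>     2% milk (125 mL, as consumed with cereal): PER 2.5 (measured) x 4.3 g protein per 125 = rating 10.8
#>     combined rating = 6.3 + 10.8 = 17.1
#>     rating 17.1 vs thresholds (>=20 good, >=40 excellent) -> none
```

Even with milk factored in, the rating (17.1) misses the 20 threshold — no
claim is possible under the current framework. Under the two proposed
frameworks the same bowl qualifies:

```r
evaluate_canada_option1(wx$foods$chickpea_cereal, wx$foods$milk_125,
                        paper_rounding = TRUE)$tier
#> [1] "good-source"    # 5 + 4.3 = 9.3 g protein per RA

r <- evaluate_canada_option2(wx$foods$chickpea_cereal, wx$foods$milk_125,
                             paper_rounding = TRUE)
r$metric_value; r$tier
#> [1] 13.8             # (0.52x5 + 1.0x4.3) = 6.9 g corrected, of 50 g DV
#> [1] "good-source"
```

Cross-jurisdiction comparison for any food:

```r
print(evaluate_all(wx$foods$bread))
#> Claim evaluation: bread (pulse and wheat blend)
#>     jurisdiction             tier   metric        basis threshold
#> 1 canada-current      good-source 20.26650          rdi        20
#> 2 canada-option1 excellent-source 10.62000           ra        10
#> 3 canada-option2           source  9.72792           ra         5
#> 4            usa             none  6.48528         racc        NA
#> 5             eu             none       NA         <NA>        NA
#> 6            anz          general  7.08000      serving         5
#> 7          codex      high-source 28.32000 nrv:per-100g        20
#> 8          china      high-source 23.60000 nrv:per-100g        20
#> 9    south-korea      high-source 25.74545 nrv:per-100g        20
```

A command-line interface (`inst/exec/proteinclaims`) wraps the same
functions: `score`, `evaluate`, `compare` and `fixtures` subcommands with
`--variant`, `--paper-rounding`, `--jurisdictions`, `--format {tsv|json}`
flags.

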