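---
title: "Protein quality scoring and claim eligibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein quality scoring and claim eligibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteinclaims)
```

# The problem

Protein content claims on food labels ("source of protein", "good source",
"excellent source", "high in protein") are regulated quantities, and the
qualifying arithmetic differs sharply between jurisdictions. Canada bases
eligibility on the protein efficiency ratio (PER) from a weanling-rat
growth bioassay; the USA on the protein digestibility corrected amino acid
score (PDCAAS); Europe on the fraction of energy from protein; Australia
and New Zealand on absolute grams per serving; and the Codex family
(including China and South Korea) on percent of a daily Nutrient Reference
Value reached through several alternative routes. A reformulated food can
qualify in one jurisdiction and fail in another on identical composition
data.

`proteinclaims` models a food once — its protein density, ingredient amino
acid profiles and digestibilities, serving bases, energy — and evaluates
all of these frameworks from that single description, with a calculation
trace for audit.

# Quality metrics

## Amino acid score and PDCAAS

For a protein with indispensable amino acid contents $aa_a$ (mg per g
protein) and a reference population requirement pattern $ref_a$, the amino
acid score is $\min_a aa_a / ref_a$, attained at the *limiting* amino
acid. Nine classes are scored; the sulphur (Met+Cys) and aromatic
(Phe+Tyr) amino acids count as pairs. PDCAAS multiplies the score by the
protein's true fecal nitrogen digestibility $d \in (0,1]$ and truncates at
1: quality above the casein-equivalent level earns no extra credit.

Two details the implementation fixes deterministically:

* **Ties.** If two amino acids are equally limiting, the canonical
  (alphabetical) key order breaks the tie and the full tied set is
  reported.
* **Truncation order.** Truncation happens before any downstream use (the
  PER conversion, corrected protein); the raw score is retained alongside
  for audit. For mixtures, truncation applies to the mixture score only,
  never per ingredient.

## Multi-ingredient weighting: 1991 vs 2007

For a food whose protein comes from ingredients $i$ with protein shares
$w_i$ (summing to 1), profiles $aa_{i,a}$ and digestibilities $d_i$, two
weighting conventions exist:

* **1991** (the convention the USA regulations cite, and this package's
  default): form the share-weighted profile $m_a = \sum_i w_i\,aa_{i,a}$
  and weighted digestibility $D = \sum_i w_i d_i$; the raw score is
  $\min_a (m_a/ref_a) \times D$.
* **2007**: weight the *digestible* amino acid content first,
  $g_a = \sum_i w_i\,aa_{i,a}\,d_i$, then apply the weighted digestibility
  coefficient. The published description of the second step is ambiguous;
  we implement $\min_a\big(g_a/(ref_a\,D)\big)\times D$, in which the
  multiplication by $D$ cancels the normalisation, so the formula
  simplifies to $\min_a g_a/ref_a$. This reading makes the variant
  collapse exactly onto the 1991 formula whenever all $d_i$ are equal —
  the behaviour one would demand of any sensible interpretation, and a
  property the test suite verifies to 1e-12 on random mixtures. No
  published worked example distinguishes the variants numerically, so the
  choice is recorded here rather than validated against an external
  number.

Both variants are permutation invariant in the ingredient list and monotone
in the limiting amino acid's content and in digestibility; these are tested
as properties.

## PER, protein rating, corrected protein

Where no measured PER exists, the CFIA conversion
$\mathrm{PER} = \mathrm{PDCAAS} \times 2.5$ is applied to the *truncated*
score (so derived PERs lie in $[0, 2.5]$, 2.5 being the standardised
casein PER). The protein rating is PER × g protein in the RDI; corrected
protein is PDCAAS × g protein at the relevant basis, and %DV divides by
the protein Daily Value (default 50 g; 13 g for USA ages 1–3).

# The claims engine

Each jurisdiction is a JSON parameter file (tier names, inclusive
thresholds in ascending order, DV/NRV constants, energy-rule unit), loaded
by `load_jurisdiction()`; the engine interprets the file, so adding or
amending a jurisdiction requires no code change. Every bundled constant
carries a citation to the underlying regulation, and a test walks the
registry asserting this. All thresholds are inclusive (every regulatory
text prints "≥"), which the suite checks by evaluating foods exactly at
each boundary.

Design points worth recording:

* **Combination rules.** PERs are not additive, and the only sanctioned
  combination under the current Canadian framework is a declared pair —
  breakfast cereal with 125 mL milk, the cereal's RDI switching to its
  combined-consumption value (30 g). `food()` therefore carries an
  explicit `companion_rdi_g`; evaluating with a companion is an error
  unless the pair is declared. The proposed Option 1/Option 2 frameworks
  combine by plain summation (grams, or corrected grams before %DV).
* **RDI fallback.** When a food has no RDI (pancakes, for example) the
  reference amount is used for the protein rating, and the substitution is
  flagged in the trace.
* **Two-tier vs three-tier.** The current Canadian framework treats
  "source" and "good source" as equivalent, so `evaluate_canada_current()`
  awards good-source/excellent-source only; Option 2 is three-tier
  (source / good source / excellent source).
* **NRV family.** Codex, China and South Korea qualify a food if *any*
  applicable route meets its threshold (per 100 g solids at 10% NRV, per
  100 mL liquids at 5%, per 100 kcal — 420 kJ for China — at 5%, per
  serving at 10% for Codex and South Korea only), and "high in protein"
  needs double the source level on some route. Every evaluable route's
  value is retained in the result; the reported metric is the qualifying
  route with the largest margin over its threshold. Liquids are stored per
  100 mL with an explicit unit kind — unit semantics are never inferred
  from magnitude, because these rules branch on solid vs liquid.
* **Energy conversion.** The protein energy factor is the Atwater 4 kcal/g
  (17 kJ/g), and kJ↔kcal conversion uses 4.184; both are configurable
  (the EU factor ships as a cited constant in its rules file).
* **Batch behaviour.** `evaluate_all()` never fails a batch: a
  jurisdiction lacking required data (no energy, no serving, no quality
  score, undeclared companion) yields tier `"none"` with the reason in the
  trace.

# Rounding

All computation is performed unrounded; `round_half_up()` (half away from
zero, the label convention — note base R's `round()` is half-to-even) is
applied only at display, or, under the optional `paper_rounding` flag,
at the specific intermediate points where published regulatory worked
tables round to one decimal: protein grams and per-food ratings for the
rating metric, per-food grams for the Option 1 metric, and the final %DV
for the PDCAAS-based metrics. The published tables themselves are not
internally consistent about this — their cereal example computes
2.32 × 2.5 = 5.8 from rounded grams at a 28 g RDI while their pancake
rating 46.7 only follows from unrounded grams (rounded grams give 46.6) —
which is exactly why the flag exists and why corrected grams are never
rounded before summing in the %DV metrics (rounding them would turn the
bread Option 2 value from the printed 9.7 into 9.8).

# Worked-example fixtures

`worked_examples()` builds the foods used throughout the documentation and
tests: soy- and chickpea-based high-density cereals (5 g protein per 55 g
RA; PER 2.0 and 2.32; chickpea PDCAAS 0.52), 125 mL 2% milk (4.3 g
protein; PER 2.5; PDCAAS 1.0), and four reformulated market foods — bread
(PDCAAS 0.458), a low-density breakfast cereal (0.671), pancake mix
(0.901) and a tricolour pasta (0.549).

The published tables print protein *per basis*, not per 100 g, and not
always self-consistently; each fixture's density was back-derived so that
one density reproduces every arithmetically consistent printed cell:

| food | density (g/100 g or mL) | derivation |
|---|---|---|
| cereals (high-density) | 9.0909 | 5 g / 55 g RA |
| milk | 3.44 | 4.3 g / 125 mL |
| bread | 14.16 | 17.7 g / 125 g RDI |
| low-density cereal | 18.4 | only value consistent with 7.4 g/40 g RACC, 5.5 g/30 g RA and the row's %DV cells |
| pancake mix | 27.6364 | 30.4 g / 110 g RACC |
| pasta | 14.8 | only value consistent with 12.6 g/85 g RDI, 8.1 g/55 g RACC and 8.9 %DV |

Three published cells are arithmetically irreproducible from any single
density and are excluded from the expected-results fixture: the milk
rating printed as 6.8 (2.5 × 4.3 = 10.75, printed 10.8 elsewhere in the
same source), the combined cereal-plus-milk rating 16.1 that inherits it,
and the pancake Option 1 cell printed 20.8 (the same row's RACC cell
implies 20.73 → 20.7, which is what the fixture asserts). Likewise a
narrative value of 5.9 for the cereal-alone rating corresponds to the
unrounded computation (2.32 × 2.545 = 5.906) while the table's 5.8 is the
paper-rounding result (2.32 × 2.5); the fixture asserts the table value
under `paper_rounding = TRUE`.

# Reference data

The scoring pattern bundled as the default is the FAO/WHO 1991 preschool
(2–5 y) pattern (His 19, Ile 28, Leu 66, Lys 58, Met+Cys 25, Phe+Tyr 63,
Thr 34, Trp 11, Val 35 mg/g protein), transcribed from the 1991 expert
consultation report. It is external reference data, marked as such in the
file, and swappable via `load_scoring_pattern(path =)` — requirements for
reference populations are periodically revised, so the pattern is
incorporated by reference rather than hard-coded. Missing amino acid
entries in any profile are an error, never imputed as zero: a silent zero
would manufacture a spurious limiting amino acid.

The serving-basis registry records the regulated RDI/RA/RACC amounts for
the covered food categories (e.g. milk: RA 250 mL, RDI 852 mL, 125 mL when
consumed with cereal) with citations; foods outside the registry require
user-supplied bases.

# Synthetic foods and what the tests show

`generate_synthetic_foods()` draws foods for property testing: 1–4
ingredients per food with shares renormalised from uniform draws,
digestibilities uniform on [0.5, 1] (the realistic range for human foods,
from well-digested animal proteins down to fibre-bound plant matrices),
per-amino-acid profile multipliers uniform on [0.3, 2] around the base
pattern (spanning the score = 1 boundary so truncation is exercised from
both sides), protein densities on [1, 40] g/100 g, serving sizes on
[20, 300] g/mL and energy densities on [50, 500] kcal/100 g. One seeded
generator drives all draws; the caller's RNG state is saved and restored,
and the same spec always serialises to identical output.

The property suite runs the brute-force amino acid score oracle on random
profile/pattern pairs, a straight-line two-step re-implementation of the
1991 mixture formula on random mixtures, the 1991 ≡ 2007 agreement under
equal digestibilities (10⁴ mixtures, 1e-12), PDCAAS bounds with truncation
engaging exactly above 1, and tier monotonicity in protein content across
all nine jurisdictions (20 synthetic foods scaled up 1.8×). These sizes
keep the full suite under half a minute while exercising each property
across its domain. The generator emulates composition ranges, not real
food chemistry: amino acid profiles are independent across ingredients and
unconstrained by biology, so passing tests demonstrate the arithmetic and
rule logic, not nutritional realism of any particular food.

# Limitations

* PER and digestibility are always inputs; the rat bioassay and
  digestibility assays (in vivo or in vitro) are out of scope, as is DIAAS
  (ileal digestibility) scoring.
* Infant foods (≤ 12 months) are rejected by the USA evaluator: that
  population's claims require the PER bioassay.
* The engine covers the numeric eligibility rules only — no claim wording
  generation, and no legal interpretation beyond the published thresholds.
* Nutrients other than protein, amino acids, digestibility and energy are
  not modelled.
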