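---
title: "CaFRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CaFRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafri)
```

## What CaFRI measures

The Carbon Footprint Reduction Index grades the *effort* an analytical
procedure makes to reduce its carbon footprint, not the footprint
itself. It is a rubric: 19 criteria in 8 categories, each answered by
selecting one option worth 1–5 points, with the point weights encoding
each criterion's importance for greenhouse-gas impact (the electricity
emission factor and instrument power, at 5 points, outweigh storage or
transportation, at 2–3). This deliberately trades fidelity for
usability: no run times, no kWh accounting, no CO₂-equivalent
quantities, and therefore no pretense of comparability with life-cycle
assessment or IPCC-style inventories. Its natural use is comparative —
ranking candidate methods for the same analyte and pointing at the
criteria (the red pictogram zones) where a method loses ground.

## The score and its normalization

With $p_i$ the points of criterion $i$'s selected option,

$$\mathrm{CaFRI} = \left\lfloor \frac{100}{65} \sum_{i=1}^{19} p_i \right\rfloor,$$

where 65 is the best achievable raw total (the sum of the best options,
obtained by enumeration of the rubric) and 19 the worst, so scores live
in [29, 100]. Two numerical decisions deserve a note:

* **Truncation, not rounding.** The published worked assessments are all
  reproduced by truncation (41 → 63.08 → 63, 50 → 76.92 → 76,
  53 → 81.54 → 81), while rounding would yield 63/77/82. Truncation also
  preserves strict monotonicity: since $100/65 > 1$, raising any single
  answer by at least one point strictly raises the score.
* **Fixed denominator.** The denominator stays 65 even when the three
  transport sub-questions are inapplicable (see the gate below), so
  scores are always comparable across methods.

The published interpretation bands translate exactly to raw points
under this normalization: scores of 50–74 ("acceptable measures")
correspond to raw totals 33–48, and scores ≥ 75 ("appreciable efforts")
to totals ≥ 49. The test suite verifies this by constructing a sheet at
every achievable raw total from 19 to 65.

## Band classifiers and edge handling

Ten criteria have numeric answer bands (instrument power, throughput,
emission factor, distance, shipment size, personnel count, waste
amount, hazard-pictogram count, solvent volume, reagent amount), and
the package accepts raw measured values for them, classifying during
scoring and recording the conversion in the breakdown
(`converted_from`). Band edges follow one rule everywhere: **a shared
edge belongs to the better-scoring band whose printed range includes
it**. Exactly 1.5 kW is "0.1–1.5 kW" (3 points), exactly 30 samples/h
is "10–30" (2 points), and — decisive for the fourth bundled case
study, whose measured factor is exactly 0.30 kg CO₂e/kWh — exactly 0.30
is "0.1–0.3 kg CO₂/kWh" (3 points). That middle-band placement is the
only reading under which the case's raw total reaches 53 and its
published score of 81 is reproduced; the same rule is then applied to
every banded criterion for consistency.

## Conservative fallbacks

Two estimation helpers follow a shared conservative principle: when a
quantity is unverified, assume the unfavorable end.

* `estimate_total_power()` sums instrument draws and, for techniques
  resolved through the bundled power-range table (17 techniques with
  aliases), uses the **maximum** of the expected range. Measured values
  (wattmeter readings) override the table. A `use = "midpoint"` mode
  exists for sensitivity exploration and announces itself with a
  message, since it departs from the default assessment rule.
* `country_emission_factor()` returns the bundled grid-intensity
  default for a country (g CO₂e/kWh, converted to kg, with a vintage
  year). An unknown country yields `source = "assumed_worst"` with
  0.5 kg CO₂e/kWh — firmly in the 1-point band — plus a warning. The
  bundled CSV holds approximate 2023 values and is meant to be edited:
  grid mixes drift, and a value near the 0.1 or 0.3 boundary is worth
  verifying against a current source before it decides a band.

## The transport gate

When `transport_required` is "No", the rubric gives no instruction for
the three transport sub-questions. The package treats them as
inapplicable and awards their best-option points (3, 4, 2): absence of
transport is at least as good as ideal transport, and the fixed
denominator is preserved. This is an interpretation, documented as
such; it keeps the all-best sheet at exactly 65 points. Answering a
gated criterion anyway is legal but flagged as a warning and ignored in
scoring, so a sheet cannot be penalized through a question that does
not apply to it.

## Colors

A criterion is green iff its best option was selected, red iff its
worst, yellow otherwise. Two-option criteria are therefore always green
or red — a transported sample ("Yes", 1 of 2 points) is a red zone even
though transport contributes little to the total. This is the rule
applied uniformly; narrative summaries of the original worked
assessments mention only the most consequential red zones, but the
pictogram shows all of them.

## Case-study fixtures and the defaults they need

Five answer sheets ship as YAML fixtures, each answer tagged `stated`
(explicit in the published case description) or `default`. Defaults
were fixed by **exhaustive consistency**, not by guessing laboratory
practice: for each case, all combinations of the unstated options were
enumerated and the combination(s) reproducing the published score kept.
For cases 1, 3 and 4 that combination is unique (case 1:
no energy-intensive auxiliary equipment and 2–10 samples per shipment;
case 3: no auxiliary equipment and semiautomatic operation; case 4: no
auxiliary equipment), which is why those three serve as exact
regression targets.

Two fixtures are *not* exact. The ritonavir case's published score (69)
exceeds what its stated answers can reach under any completion (at most
44 points → 67); it ships with conservative defaults and an
`expected_total_points: unresolved` marker. The supplementary LC-MS/MS
comparison's answers were never published in the running text; its
fixture is a clearly-labelled synthetic reconstruction, and its printed
score (62) is unreachable under truncation by any integer total
(40 → 61, 41 → 63), suggesting the original tooling rounded. Both are
excluded from exactness tests and documented inside their YAML files.

## The random-sheet generator

`generate_random_sheet()` supports property testing: one option
uniformly at random per criterion, the transport gate closed with
probability ½ (gated criteria then omitted), fully reproducible from a
seed, and RNG-state neutral. It emulates the combinatorial breadth of
the questionnaire, not the correlations of real laboratories — real
methods do not choose "no storage" independently of "> 30 samples/h".
Passing property tests therefore demonstrate the engine's arithmetic
(agreement with an independently transcribed brute-force point table on
1000 generated sheets, monotonicity under single-answer upgrades,
category subtotals partitioning the total, pictogram colors matching
the breakdown), not anything about the distribution of real methods'
scores.

## Pictogram layout

Only the concept of the output figure is fixed — a human foot whose
zones are colored red/yellow/green per criterion with the score as a
numeral. The geometry here is this package's own: heel = energy + CO₂
emission, arch = storage + transportation (numeral in the middle),
ball = personnel + waste, toes = recycling + reagents/solvents. Zones
are SVG circles with machine-readable ids (`zone-<criterion>`), the
palette is fixed (`#d62728`/`#f2c200`/`#2ca02c`), and rendering is a
pure function of the breakdown, byte-identical across calls — which is
what lets tests compare the SVG's color histogram against the
breakdown's without image processing.

## Problem sizes and test budget

The suite is deliberately exhaustive where the space is small —
all 47 achievable raw totals for the band-inversion check, every
technique in the power table, every case fixture — and sampled where it
is not: 1000 seeded random sheets for the oracle-equivalence property,
200 for monotonicity, 50 for SVG/breakdown histogram equality, 1000 for
generator coverage of every option of every criterion. These sizes keep
the full suite comfortably under a minute of scoring work while giving
each option and each band edge many hits.

## Known limitations

* The rubric is fixed by design; there is no support for user-defined
  criteria or weights, so the package cannot express disagreement with
  the published point allocation.
* Self-reported answers dominate the score; the package validates
  structure, not truthfulness, and the recommended two-evaluator
  consensus is a documentation practice outside its scope.
* Band classifiers are only as good as their inputs: the bundled power
  ranges are expert estimates and the country table is a coarse 2023
  snapshot. Both are plain CSV precisely so users can replace them.
* No CO₂e quantities are computed anywhere; a method with an excellent
  CaFRI score can still have a large absolute footprint if it is run at
  scale.
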