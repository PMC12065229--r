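# cafri — Carbon Footprint Reduction Index for analytical methods

`cafri` scores how much effort an analytical laboratory procedure makes to
reduce its carbon footprint. It implements the Carbon Footprint Reduction
Index (CaFRI), a rubric-based greenness metric for chemists: a 19-question
questionnaire covering 8 categories — energy, CO₂ emission, sample storage,
transportation, personnel, waste, recycling, and reagents/solvents — in
which every question is answered by selecting one point-valued option
(1–5 points, higher is greener). Unlike life-cycle assessment or CO₂e
inventories, CaFRI does not quantify emissions; it grades reduction
*effort* at the level of a single method, one sample analyzed being the
implicit functional unit.

## The score

Each criterion *i* awards the points $p_i$ of its selected option. The raw
total is normalized to the 0–100 CaFRI scale by truncation against the
best achievable total (65 points over the 19 criteria):

$$\mathrm{CaFRI} = \left\lfloor \frac{100 \sum_i p_i}{65} \right\rfloor$$

so the ideal method scores 100 and the worst possible configuration
(19 points) scores 29. Each criterion also gets a traffic-light color —
green for its best option, red for its worst, yellow in between — and the
result is drawn as a foot-shaped pictogram whose 19 zones carry those
colors, with the score as a central numeral. The red zones are where a
method should improve first.

Supporting pieces:

- **Instrument power.** A bundled table of expected power ranges (kW) for
  17 common techniques; unverified draws are taken at the range maximum
  (conservative rule), and the total is banded as `< 0.1` / `0.1–1.5` /
  `> 1.5` kW worth 5/3/1 points. Shared band edges belong to the
  better-scoring band (exactly 1.5 kW is the 3-point band).
- **Emission factor.** The grid carbon intensity (kg CO₂e/kWh) of the
  laboratory's electricity, banded `< 0.1` / `0.1–0.3` / `> 0.3` worth
  5/3/1 points, with an editable country-level default table bundled as
  CSV. An unknown country conservatively falls to the worst band.
- **Transport gate.** If samples need no transport, the three transport
  sub-questions (distance, shipment size, eco-vehicle) are inapplicable
  and are awarded their best points.

## Worked example

Scoring a plasma-drug assay (menthol-based microextraction followed by
HPLC/UV, autosampler, measured emission factor of 0.30 kg CO₂e/kWh,
samples stored at −80 °C). Raw measured values are accepted for the
banded criteria and classified automatically:

```r
library(cafri)

sheet <- answer_sheet("Favipiravir HLLME HPLC/UV",
  answers = list(
    energy_program           = "Yes",
    instrument_power         = estimate_total_power(c("HPLC", "UV/Vis")),  # 1.8 kW
    non_analytical_equipment = "No",
    sample_throughput        = 12,     # samples/h
    carbon_footprint_known   = "Yes",
    emission_factor          = 0.30,   # kg CO2e/kWh, measured
    sample_storage           = "Storage under special conditions (deep freezers, vacuum, high pressure)",
    transport_required       = "Yes",
    transport_distance       = "< 1 mile",
    shipment_size            = 60,
    eco_vehicle              = "Yes",
    personnel_count          = 1,
    automation               = "automatic",
    waste_amount             = "< 10 mL or g per sample",
    waste_disposal           = "Waste disposal by a specialized personnel/entity",
    recycling                = "The method employs recycled reagents/solvents from the same method",
    pictogram_count          = 5,      # GHS hazard pictograms across reagents
    organic_solvent_volume   = "< 5 mL",
    reagent_amount           = "< 1 g or mL"))

s <- cafri_score(sheet)
summary(s)
#> CaFRI assessment: Favipiravir HLLME HPLC/UV
#>
#> Per category:
#>   ENERGY             11 / 16
#>   CO2_EMISSION        7 /  9
#>   STORAGE             1 /  3
#>   TRANSPORTATION      9 / 11
#>   PERSONNEL           7 /  7
#>   WASTE               6 /  6
#>   RECYCLING           3 /  3
#>   REAGENTS_SOLVENTS   9 / 10
#>
#> Total: 53 / 65 raw points -> CaFRI score 81 / 100
#> Zones: 12 green, 4 yellow, 3 red
```

A score of 81 means strong reduction effort (75+); 50–74 is acceptable;
below 50 is poor. The three red zones (deep-freeze storage, > 1.5 kW
instruments, transported samples) are the levers for improvement.
`render_pictogram(s, "foot.svg")` writes the foot pictogram,
`render_report(s, "markdown")` a full report, and the bundled case
studies compare as:

```r
compare_sheets(lapply(c(1, 3, 4), function(i) load_case_fixture(i)$sheet))
#> CaFRI comparison (best first):
#>                                      method_name total_points normalized_score red_zones
#> 1     Favipiravir menthol HLLME HPLC/UV (case 4)           53               81         3
#> 2 Molnupiravir carbon-quantum-dot assay (case 3)           50               76         4
#> 3  Polidocanol spectrophotometric assay (case 1)           41               63         8
```

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cafri.R", package = "cafri"))') \
    score answers.yaml --svg foot.svg --report report.md
```

with subcommands `score`, `compare`, `rubric`, `power`, `fixtures`
(exit codes: 0 success, 2 validation failure, 1 internal error).

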