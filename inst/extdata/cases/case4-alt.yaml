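# Supplementary comparison: an alternative LC-MS/MS method for
# favipiravir, published score 62. SYNTHETIC ILLUSTRATIVE fixture: the
# underlying answers appear only in supplementary material not
# available here; this sheet is a plausible reconstruction from the
# narrative remarks (energy-intensive LC-MS/MS, specialized personnel,
# no recycling, high CO2 emission) and carries NO exactness claim.
case: "4-alt"
method_name: "Favipiravir LC-MS/MS alternative (case 4-alt, synthetic)"
expected_score: 62
expected_total_points: unresolved
answers:
  energy_program: "Yes"
  instrument_power: "> 1.5 kW"
  non_analytical_equipment: "Yes"
  sample_throughput: "< 10 samples/h"
  carbon_footprint_known: "No"
  emission_factor: "> 0.3 kg CO2/kWh"
  sample_storage: "Storage under special conditions (deep freezers, vacuum, high pressure)"
  transport_required: "Yes"
  transport_distance: "< 1 mile"
  shipment_size: "11–100 samples per shipment"
  eco_vehicle: "Yes"
  personnel_count: "2–3 persons"
  automation: "automatic"
  waste_amount: "< 10 mL or g per sample"
  waste_disposal: "Waste disposal by the analyst"
  recycling: "No recycling is performed"
  pictogram_count: "4–6"
  organic_solvent_volume: "< 5 mL"
  reagent_amount: "< 1 g or mL"
provenance:
  instrument_power: "stated (energy-intensive LC-MS/MS)"
  recycling: "stated (waste recycling suggested as an improvement)"
  emission_factor: "stated (CO2 emission flagged as an improvement area)"
  personnel_count: "stated (requires specialized personnel)"
notes: >
  Illustrative only. This reconstruction totals 40 raw points (score 61
  under the truncating normalization); no integer raw total maps to the
  printed 62 under truncation (40 -> 61, 41 -> 63), which suggests the
  original assessment rounded. Excluded from all exactness tests.
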