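# Case study 1: spectrophotometric determination of polidocanol in
# commercial ampoules (ternary complex with cobalt(II)-thiocyanate,
# absorbance at 320 nm). Published assessment: CaFRI score 63.
case: "1"
method_name: "Polidocanol spectrophotometric assay (case 1)"
expected_score: 63
expected_total_points: 41
answers:
  energy_program: "Yes"
  instrument_power: "> 1.5 kW"
  non_analytical_equipment: "No"
  sample_throughput: 8
  carbon_footprint_known: "No"
  emission_factor: "> 0.3 kg CO2/kWh"
  sample_storage: "Storage under normal conditions (refrigerators)"
  transport_required: "Yes"
  transport_distance: "< 1 mile"
  shipment_size: "2–10 samples per shipment"
  eco_vehicle: "Yes"
  personnel_count: "2–3 persons"
  automation: "manual"
  waste_amount: "< 10 mL or g per sample"
  waste_disposal: "No waste disposal is performed"
  recycling: "No recycling is performed"
  pictogram_count: 3
  organic_solvent_volume: "< 5 mL"
  reagent_amount: "< 1 g or mL"
provenance:
  energy_program: stated
  instrument_power: stated
  non_analytical_equipment: default
  sample_throughput: "stated (8 samples/h)"
  carbon_footprint_known: stated
  emission_factor: stated
  sample_storage: stated
  transport_required: stated
  transport_distance: stated
  shipment_size: default
  eco_vehicle: "stated (compressed natural gas vehicles)"
  personnel_count: stated
  automation: stated
  waste_amount: stated
  waste_disposal: stated
  recycling: stated
  pictogram_count: "stated (three pictograms)"
  organic_solvent_volume: stated
  reagent_amount: stated
notes: >
  The two answers tagged "default" are not stated in the published case
  description. They are fixed by exhaustive consistency: among all 8
  combinations of the unstated options, only non-analytical equipment =
  "No" (4 pts) with shipment size "2–10" (2 pts) reproduces the printed
  score of 63 (raw total 41).
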