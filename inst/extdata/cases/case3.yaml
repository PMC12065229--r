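# Case study 3: determination of molnupiravir in hard gelatin capsules
# via eggshell-derived carbon quantum dots. Published assessment:
# CaFRI score 76.
case: "3"
method_name: "Molnupiravir carbon-quantum-dot assay (case 3)"
expected_score: 76
expected_total_points: 50
answers:
  energy_program: "Yes"
  instrument_power: "< 0.1 kW"
  non_analytical_equipment: "No"
  sample_throughput: "> 30 samples/h"
  carbon_footprint_known: "No"
  emission_factor: "> 0.3 kg CO2/kWh"
  sample_storage: "Storage under normal conditions (refrigerators)"
  transport_required: "Yes"
  transport_distance: "< 1 mile"
  shipment_size: 50
  eco_vehicle: "Yes"
  personnel_count: "1 person"
  automation: "semiautomatic"
  waste_amount: "< 10 mL or g per sample"
  waste_disposal: "Waste disposal by the analyst"
  recycling: "No recycling is performed"
  pictogram_count: 6
  organic_solvent_volume: "< 5 mL"
  reagent_amount: "< 1 g or mL"
provenance:
  energy_program: stated
  instrument_power: stated
  non_analytical_equipment: default
  sample_throughput: stated
  carbon_footprint_known: stated
  emission_factor: stated
  sample_storage: "stated (storage at normal conditions)"
  transport_required: stated
  transport_distance: stated
  shipment_size: "stated (50 samples per shipment)"
  eco_vehicle: stated
  personnel_count: stated
  automation: default
  waste_amount: stated
  waste_disposal: stated
  recycling: stated
  pictogram_count: "stated (six pictograms)"
  organic_solvent_volume: stated
  reagent_amount: stated
notes: >
  The two answers tagged "default" are not stated in the published case
  description. They are fixed by exhaustive consistency: among all 6
  combinations of the unstated options, only non-analytical equipment =
  "No" (4 pts) with semiautomatic operation (2 pts) reproduces the
  printed score of 76 (raw total 50).
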