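# Case study 2: dispersive solid-phase microextraction of ritonavir
# from human plasma on a cellulose/MOF hybrid sorbent, HPLC/UV
# quantification. Published assessment: CaFRI score 69 — NOT reproduced
# by this fixture; see notes.
case: "2"
method_name: "Ritonavir MOF d-SPME HPLC/UV (case 2)"
expected_score: 69
expected_total_points: unresolved
answers:
  energy_program: "Yes"
  instrument_power: "> 1.5 kW"
  non_analytical_equipment: "No"
  sample_throughput: 4
  carbon_footprint_known: "No"
  emission_factor: "> 0.3 kg CO2/kWh"
  sample_storage: "Storage under special conditions (deep freezers, vacuum, high pressure)"
  transport_required: "Yes"
  transport_distance: "< 1 mile"
  shipment_size: 10
  eco_vehicle: "Yes"
  personnel_count: "2–3 persons"
  automation: "manual"
  waste_amount: "< 10 mL or g per sample"
  waste_disposal: "No waste disposal is performed"
  recycling: "The method employs recycled reagents/solvents from the same method"
  pictogram_count: 3
  organic_solvent_volume: "< 5 mL"
  reagent_amount: "< 1 g or mL"
provenance:
  energy_program: stated
  instrument_power: stated
  non_analytical_equipment: default
  sample_throughput: "stated (4 samples/h)"
  carbon_footprint_known: stated
  emission_factor: stated
  sample_storage: "stated (storage at -80 C)"
  transport_required: stated
  transport_distance: stated
  shipment_size: "stated (10 samples per shipment)"
  eco_vehicle: stated
  personnel_count: stated
  automation: default
  waste_amount: stated
  waste_disposal: stated
  recycling: "stated (MOF recycled for reuse in the same method)"
  pictogram_count: "stated (three pictograms)"
  organic_solvent_volume: stated
  reagent_amount: stated
notes: >
  Known discrepancy. The published score is 69, but the answers stated
  in the case description sum to at most 44 raw points (score 67) even
  when both unstated items take their best options; no consistent
  completion reaches 69. This fixture ships the stated answers with
  conservative defaults (no energy-intensive non-analytical equipment,
  manual operation; raw total 42, score 64) and is excluded from
  exactness tests. The original assessment may have used answers not
  stated in the text.
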