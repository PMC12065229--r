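{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "CaFRI answer sheet",
  "description": "One analytical method's questionnaire responses. Keys of 'answers' are the 19 criterion ids; each value is either the verbatim option label or, for criteria with numeric bands (instrument_power, sample_throughput, emission_factor, transport_distance, shipment_size, personnel_count, waste_amount, pictogram_count, organic_solvent_volume, reagent_amount), a raw measured value in the criterion's unit. transport_distance, shipment_size and eco_vehicle may be omitted when transport_required is \"No\".",
  "type": "object",
  "required": ["answers"],
  "properties": {
    "method_name": {"type": "string"},
    "answers": {
      "type": "object",
      "propertyNames": {
        "enum": [
          "energy_program", "instrument_power", "non_analytical_equipment",
          "sample_throughput", "carbon_footprint_known", "emission_factor",
          "sample_storage", "transport_required", "transport_distance",
          "shipment_size", "eco_vehicle", "personnel_count", "automation",
          "waste_amount", "waste_disposal", "recycling", "pictogram_count",
          "organic_solvent_volume", "reagent_amount"
        ]
      },
      "additionalProperties": {"type": ["string", "number"]}
    },
    "metadata": {
      "type": "object",
      "properties": {
        "country": {"type": "string"},
        "measured_emission_factor": {
          "type": "number",
          "description": "kg CO2e per kWh"
        },
        "instruments": {"type": "array", "items": {"type": "string"}},
        "notes": {"type": "string"}
      }
    }
  }
}
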