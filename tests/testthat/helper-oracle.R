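# Independent brute-force scoring oracle. This walks a flat transcription
# of the published point table directly — deliberately sharing no code or
# data structures with the package's rubric — so agreement between the
# two is a meaningful check.

oracle_ids <- c(
  "energy_program", "instrument_power", "non_analytical_equipment",
  "sample_throughput", "carbon_footprint_known", "emission_factor",
  "sample_storage", "transport_required", "transport_distance",
  "shipment_size", "eco_vehicle", "personnel_count", "automation",
  "waste_amount", "waste_disposal", "recycling", "pictogram_count",
  "organic_solvent_volume", "reagent_amount")

oracle_points <- list(
  energy_program = c("yes" = 4, "no" = 1),
  instrument_power = c("< 0.1 kw" = 5, "0.1–1.5 kw" = 3,
                       "> 1.5 kw" = 1),
  non_analytical_equipment = c("yes" = 1, "no" = 4),
  sample_throughput = c("> 30 samples/h" = 3, "10–30 samples/h" = 2,
                        "< 10 samples/h" = 1),
  carbon_footprint_known = c("yes" = 4, "no" = 1),
  emission_factor = c("< 0.1 kg co2/kwh" = 5, "0.1–0.3 kg co2/kwh" = 3,
                      "> 0.3 kg co2/kwh" = 1),
  sample_storage = c("no storage was required" = 3,
                     "storage under normal conditions (refrigerators)" = 2,
                     "storage under special conditions (deep freezers, vacuum, high pressure)" = 1),
  transport_required = c("no" = 2, "yes" = 1),
  transport_distance = c("< 1 mile" = 3, "1–10 miles" = 2,
                         "> 10 miles" = 1),
  shipment_size = c("> 100 samples per shipment" = 4,
                    "11–100 samples per shipment" = 3,
                    "2–10 samples per shipment" = 2,
                    "1 sample per shipment" = 1),
  eco_vehicle = c("yes" = 2, "no" = 1),
  personnel_count = c("1 person" = 4, "2–3 persons" = 3,
                      "4–5 persons" = 2, "> 5 persons" = 1),
  automation = c("automatic" = 3, "semiautomatic" = 2, "manual" = 1),
  waste_amount = c("< 10 ml or g per sample" = 3,
                   "10–100 ml or g per sample" = 2,
                   "> 100 ml or g per sample" = 1),
  waste_disposal = c("waste disposal by a specialized personnel/entity" = 3,
                     "waste disposal by the analyst" = 2,
                     "no waste disposal is performed" = 1),
  recycling = c("the method employs recycled reagents/solvents from the same method" = 3,
                "the method employs recycled reagents/solvents from other methods" = 2,
                "no recycling is performed" = 1),
  pictogram_count = c("≤ 3" = 4, "4–6" = 3, "7–9" = 2,
                      "> 9" = 1),
  organic_solvent_volume = c("< 5 ml" = 3, "5–10 ml" = 2, "> 10 ml" = 1),
  reagent_amount = c("< 1 g or ml" = 3, "1–3 g or ml" = 2,
                     "> 3 g or ml" = 1))

# numeric-band fallback for raw measured answers; shared edges belong to
# the better-scoring band whose printed range includes them
oracle_band_points <- function(id, v) {
  switch(id,
    instrument_power = if (v < 0.1) 5 else if (v <= 1.5) 3 else 1,
    emission_factor = if (v < 0.1) 5 else if (v <= 0.3) 3 else 1,
    sample_throughput = if (v > 30) 3 else if (v >= 10) 2 else 1,
    transport_distance = if (v < 1) 3 else if (v <= 10) 2 else 1,
    shipment_size = if (v > 100) 4 else if (v >= 11) 3 else if (v >= 2) 2 else 1,
    personnel_count = if (v == 1) 4 else if (v <= 3) 3 else if (v <= 5) 2 else 1,
    waste_amount = if (v < 10) 3 else if (v <= 100) 2 else 1,
    pictogram_count = if (v <= 3) 4 else if (v <= 6) 3 else if (v <= 9) 2 else 1,
    organic_solvent_volume = if (v < 5) 3 else if (v <= 10) 2 else 1,
    reagent_amount = if (v < 1) 3 else if (v <= 3) 2 else 1,
    stop("oracle: no numeric bands for ", id))
}

oracle_total <- function(sheet) {
  a <- sheet$answers
  transport_no <- !is.null(a$transport_required) &&
    tolower(trimws(as.character(a$transport_required))) == "no"
  gated_best <- c(transport_distance = 3, shipment_size = 4, eco_vehicle = 2)
  total <- 0
  for (id in oracle_ids) {
    if (transport_no && id %in% names(gated_best)) {
      total <- total + gated_best[[id]]
      next
    }
    v <- a[[id]]
    if (is.numeric(v)) {
      total <- total + oracle_band_points(id, v)
    } else {
      key <- tolower(trimws(gsub("[[:space:]]+", " ", as.character(v))))
      pts <- oracle_points[[id]][key]
      if (is.na(pts)) stop("oracle: unknown label ", v, " for ", id)
      total <- total + pts
    }
  }
  as.integer(total)
}

oracle_score <- function(sheet) {
  as.integer((oracle_total(sheet) * 100) %/% 65)
}
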