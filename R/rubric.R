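#' The CaFRI scoring rubric
#'
#' Builds the fixed Carbon Footprint Reduction Index (CaFRI) rubric: 19
#' criteria in 8 categories, each criterion offering 2--4 answer options
#' worth 1--5 points (best option first). The rubric is the single source
#' of truth consumed by scoring, classification and rendering.
#'
#' Categories and their criterion counts: ENERGY (4), CO2_EMISSION (2),
#' STORAGE (1), TRANSPORTATION (4), PERSONNEL (2), WASTE (2), RECYCLING (1),
#' REAGENTS_SOLVENTS (3). The three transport sub-questions
#' (`transport_distance`, `shipment_size`, `eco_vehicle`) are gated by
#' `transport_required`: when no transport is needed they are inapplicable
#' and scored at their best-option points.
#'
#' Criteria whose options are numeric bands additionally carry
#' machine-readable interval bounds, so raw measured values can be
#' classified into the band labels (see [classify_band()]). Shared band
#' edges always belong to the better-scoring band that names them
#' (e.g. exactly 1.5 kW falls in "0.1–1.5 kW", exactly 0.3 kg CO2/kWh in
#' "0.1–0.3 kg CO2/kWh").
#'
#' @return An immutable object of class `cafri_rubric`: a list with
#'   `categories` (data.frame: `id`, `display_name`), `criteria` (named
#'   list of criterion records in rubric order), `max_total_points` (65)
#'   and `min_total_points` (19).
#' @examples
#' r <- cafri_rubric()
#' r$max_total_points
#' find_criterion(r, "emission_factor")$options
#' @export
cafri_rubric <- function() {
  categories <- data.frame(
    id = c("ENERGY", "CO2_EMISSION", "STORAGE", "TRANSPORTATION",
           "PERSONNEL", "WASTE", "RECYCLING", "REAGENTS_SOLVENTS"),
    display_name = c("Energy", "CO2 emission", "Storage", "Transportation",
                     "Personnel", "Waste", "Recycling", "Reagents/solvents"),
    stringsAsFactors = FALSE
  )

  # helper: one criterion record; options best-first, points strictly
  # decreasing; bands (optional) parallel the options as c(lo, hi,
  # lo_open, hi_open) with open bounds encoded as 1
  cr <- function(id, category, question, labels, points,
                 gated_by = NA_character_, bands = NULL, unit = NA_character_) {
    stopifnot(length(labels) == length(points), all(diff(points) < 0))
    list(
      id = id, category = category, question = question,
      options = data.frame(label = labels, points = as.integer(points),
                           stringsAsFactors = FALSE),
      gated_by = gated_by, bands = bands, unit = unit
    )
  }
  band <- function(lo, hi, lo_open = FALSE, hi_open = FALSE) {
    list(lo = lo, hi = hi, lo_open = lo_open, hi_open = hi_open)
  }

  criteria <- list(
    cr("energy_program", "ENERGY",
       "An energy reduction program or clean energy sources are adapted throughout the procedures",
       c("Yes", "No"), c(4, 1)),
    cr("instrument_power", "ENERGY",
       "Total electrical power use of analytical instruments",
       c("< 0.1 kW", "0.1–1.5 kW", "> 1.5 kW"), c(5, 3, 1),
       bands = list(band(0, 0.1, hi_open = TRUE),
                    band(0.1, 1.5),
                    band(1.5, Inf, lo_open = TRUE)),
       unit = "kW"),
    cr("non_analytical_equipment", "ENERGY",
       "Energy-intensive non-analytical equipment is essential (fume hood, air conditioners)",
       c("No", "Yes"), c(4, 1)),
    cr("sample_throughput", "ENERGY",
       "Number of samples analyzed per hour",
       c("> 30 samples/h", "10–30 samples/h", "< 10 samples/h"), c(3, 2, 1),
       bands = list(band(30, Inf, lo_open = TRUE),
                    band(10, 30),
                    band(0, 10, hi_open = TRUE)),
       unit = "samples/h"),
    cr("carbon_footprint_known", "CO2_EMISSION",
       "The carbon footprint of the electrical power of analytical instruments is known",
       c("Yes", "No"), c(4, 1)),
    cr("emission_factor", "CO2_EMISSION",
       "Emission factor",
       c("< 0.1 kg CO2/kWh", "0.1–0.3 kg CO2/kWh", "> 0.3 kg CO2/kWh"),
       c(5, 3, 1),
       bands = list(band(0, 0.1, hi_open = TRUE),
                    band(0.1, 0.3),
                    band(0.3, Inf, lo_open = TRUE)),
       unit = "kg CO2/kWh"),
    cr("sample_storage", "STORAGE",
       "Sample Storage",
       c("No storage was required",
         "Storage under normal conditions (refrigerators)",
         "Storage under special conditions (deep freezers, vacuum, high pressure)"),
       c(3, 2, 1)),
    cr("transport_required", "TRANSPORTATION",
       "The sample has to be transported to an analytical Laboratory",
       c("No", "Yes"), c(2, 1)),
    cr("transport_distance", "TRANSPORTATION",
       "Distance between the sample field and the laboratory",
       c("< 1 mile", "1–10 miles", "> 10 miles"), c(3, 2, 1),
       gated_by = "transport_required",
       bands = list(band(0, 1, hi_open = TRUE),
                    band(1, 10),
                    band(10, Inf, lo_open = TRUE)),
       unit = "miles"),
    cr("shipment_size", "TRANSPORTATION",
       "Number of samples transported in one shipment",
       c("> 100 samples per shipment", "11–100 samples per shipment",
         "2–10 samples per shipment", "1 sample per shipment"),
       c(4, 3, 2, 1),
       gated_by = "transport_required",
       bands = list(band(100, Inf, lo_open = TRUE),
                    band(11, 100),
                    band(2, 10),
                    band(1, 1)),
       unit = "samples per shipment"),
    cr("eco_vehicle", "TRANSPORTATION",
       "An ecofriendly vehicle is used in transportation",
       c("Yes", "No"), c(2, 1),
       gated_by = "transport_required"),
    cr("personnel_count", "PERSONNEL",
       "Number of personnel required for one sample analysis",
       c("1 person", "2–3 persons", "4–5 persons", "> 5 persons"),
       c(4, 3, 2, 1),
       bands = list(band(1, 1),
                    band(2, 3),
                    band(4, 5),
                    band(5, Inf, lo_open = TRUE)),
       unit = "persons"),
    cr("automation", "PERSONNEL",
       "Automation",
       c("automatic", "semiautomatic", "manual"), c(3, 2, 1)),
    cr("waste_amount", "WASTE",
       "Waste amount",
       c("< 10 mL or g per sample", "10–100 mL or g per sample",
         "> 100 mL or g per sample"), c(3, 2, 1),
       bands = list(band(0, 10, hi_open = TRUE),
                    band(10, 100),
                    band(100, Inf, lo_open = TRUE)),
       unit = "mL or g per sample"),
    cr("waste_disposal", "WASTE",
       "Waste disposal",
       c("Waste disposal by a specialized personnel/entity",
         "Waste disposal by the analyst",
         "No waste disposal is performed"), c(3, 2, 1)),
    cr("recycling", "RECYCLING",
       "Recycling",
       c("The method employs recycled reagents/solvents from the same method",
         "The method employs recycled reagents/solvents from other methods",
         "No recycling is performed"), c(3, 2, 1)),
    cr("pictogram_count", "REAGENTS_SOLVENTS",
       "Total number of pictograms",
       c("≤ 3", "4–6", "7–9", "> 9"), c(4, 3, 2, 1),
       bands = list(band(0, 3),
                    band(4, 6),
                    band(7, 9),
                    band(9, Inf, lo_open = TRUE)),
       unit = "pictograms"),
    cr("organic_solvent_volume", "REAGENTS_SOLVENTS",
       "Total amount of organic solvents per sample",
       c("< 5 mL", "5–10 mL", "> 10 mL"), c(3, 2, 1),
       bands = list(band(0, 5, hi_open = TRUE),
                    band(5, 10),
                    band(10, Inf, lo_open = TRUE)),
       unit = "mL"),
    cr("reagent_amount", "REAGENTS_SOLVENTS",
       "Total amount of reagents per sample",
       c("< 1 g or mL", "1–3 g or mL", "> 3 g or mL"), c(3, 2, 1),
       bands = list(band(0, 1, hi_open = TRUE),
                    band(1, 3),
                    band(3, Inf, lo_open = TRUE)),
       unit = "g or mL")
  )
  names(criteria) <- vapply(criteria, `[[`, "", "id")

  best <- vapply(criteria, function(x) max(x$options$points), 0L)
  worst <- vapply(criteria, function(x) min(x$options$points), 0L)

  structure(
    list(categories = categories,
         criteria = criteria,
         max_total_points = sum(best),
         min_total_points = sum(worst)),
    class = "cafri_rubric"
  )
}

#' Look up a criterion by id
#'
#' @param rubric A [cafri_rubric()] object.
#' @param id One of the 19 criterion identifiers.
#' @return The criterion record (list with `id`, `category`, `question`,
#'   `options`, `gated_by`, `bands`, `unit`).
#' @examples
#' find_criterion(cafri_rubric(), "instrument_power")
#' @export
find_criterion <- function(rubric, id) {
  stopifnot(inherits(rubric, "cafri_rubric"))
  if (!is.character(id) || length(id) != 1L || !id %in% names(rubric$criteria)) {
    stop("unknown criterion id ", dQuote(as.character(id)[1]),
         "; valid ids: ", paste(names(rubric$criteria), collapse = ", "),
         call. = FALSE)
  }
  rubric$criteria[[id]]
}

#' @export
print.cafri_rubric <- function(x, ...) {
  cat("CaFRI rubric:", length(x$criteria), "criteria in",
      nrow(x$categories), "categories\n")
  cat("Total points range:", x$min_total_points, "-", x$max_total_points, "\n")
  for (cid in x$categories$id) {
    crs <- Filter(function(cr) cr$category == cid, x$criteria)
    cat(sprintf("  %-18s %s\n", cid,
                paste(names(crs), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize the rubric to JSON
#'
#' Exports one record per criterion (`id`, `category`, `question`,
#' `options` with `label`/`points`, `gated_by`) as pretty-printed JSON,
#' for transparency and third-party tooling. The export round-trips: the
#' structure read back with [jsonlite::fromJSON()] carries exactly the
#' rubric's ids, labels and points.
#'
#' @param rubric A [cafri_rubric()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
rubric_to_json <- function(rubric, path = NULL) {
  stopifnot(inherits(rubric, "cafri_rubric"))
  recs <- lapply(unname(rubric$criteria), function(cr) {
    rec <- list(id = cr$id, category = cr$category, question = cr$question,
                options = cr$options)
    if (!is.na(cr$gated_by)) rec$gated_by <- cr$gated_by
    rec
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

# Normalize an answer label for comparison: collapse whitespace, lower
# case, unify dash variants to en dash, strip the subscript underscore in
# "CO_2", and accept "<=" for the '≤' sign.
normalize_label <- function(x) {
  x <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  x <- gsub("co_2", "co2", x, fixed = TRUE)
  x <- gsub("<=", "≤", x, fixed = TRUE)
  x <- gsub("—|−|-", "–", x)
  # a dash between digits may have been typed with spaces ("1 - 10")
  gsub(" ?– ?", "–", x)
}

# Match a user-supplied label against a criterion's options; returns the
# row index or NA.
match_option <- function(criterion, label) {
  m <- match(normalize_label(label), normalize_label(criterion$options$label))
  m
}

#' Classify a raw numeric value into a criterion's answer band
#'
#' For criteria whose options are numeric bands (instrument power,
#' throughput, emission factor, distance, shipment size, personnel count,
#' waste amount, pictogram count, solvent volume, reagent amount), maps a
#' measured value onto the option label and points. A value on a shared
#' band edge is placed in the better-scoring band that includes it in its
#' printed range (0.1 and 1.5 kW both fall in "0.1–1.5 kW").
#'
#' @param rubric A [cafri_rubric()] object.
#' @param id Criterion id (must be a banded criterion).
#' @param value Positive numeric measurement in the criterion's unit.
#' @return A list with `label`, `points`, `criterion`.
#' @examples
#' classify_band(cafri_rubric(), "instrument_power", 1.5)
#' @export
classify_band <- function(rubric, id, value) {
  cr <- find_criterion(rubric, id)
  if (is.null(cr$bands)) {
    stop("criterion ", dQuote(id), " has no numeric bands; answer with one of: ",
         paste(dQuote(cr$options$label), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    stop("value for ", dQuote(id), " must be a single non-negative number (",
         cr$unit, ")", call. = FALSE)
  }
  for (i in seq_along(cr$bands)) {
    b <- cr$bands[[i]]
    lo_ok <- if (b$lo_open) value > b$lo else value >= b$lo
    hi_ok <- if (b$hi_open) value < b$hi else value <= b$hi
    if (lo_ok && hi_ok) {
      return(list(label = cr$options$label[i],
                  points = cr$options$points[i],
                  criterion = id))
    }
  }
  stop("value ", value, " outside all bands of ", dQuote(id), call. = FALSE)
}
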