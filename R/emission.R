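#' Country-level electricity carbon intensity defaults
#'
#' Reads the bundled (or a user-supplied) table of grid carbon intensity
#' in g CO2e per kWh. The bundled values are approximate 2023 figures and
#' are meant as editable defaults: the CSV under
#' `system.file("extdata", "emission_factors.csv", package = "cafri")`
#' documents its own vintage and should be refreshed from a current
#' public dataset when a band assignment falls near the 0.1 or 0.3
#' kg CO2/kWh boundaries.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `country`, `g_co2e_per_kwh`, `year`, `source_note`.
#' @return data.frame with those four columns.
#' @export
emission_factor_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "emission_factors.csv", package = "cafri",
                        mustWork = TRUE)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Default emission factor for a country
#'
#' Looks a country up in the bundled carbon-intensity table and converts
#' g CO2e/kWh to kg. An unknown country falls back, conservatively, to a
#' worst-band assumption (0.5 kg CO2/kWh, i.e. the 1-point "> 0.3" band)
#' with a warning — mirroring the rule that an unverified instrument draw
#' is taken at its maximum.
#'
#' @param country Country name (case-insensitive).
#' @param table Carbon-intensity table, defaults to
#'   [emission_factor_table()].
#' @return An object of class `cafri_emission_factor`: list with `value`
#'   (kg CO2e/kWh), `source` (`"country_table"` or `"assumed_worst"`),
#'   `country`, and `year` (NA for the assumed fallback).
#' @examples
#' country_emission_factor("Sweden")
#' @export
country_emission_factor <- function(country, table = emission_factor_table()) {
  stopifnot(is.character(country), length(country) == 1L)
  hit <- which(tolower(table$country) == tolower(trimws(country)))
  if (length(hit) == 1L) {
    ef <- list(value = table$g_co2e_per_kwh[hit] / 1000,
               source = "country_table",
               country = table$country[hit],
               year = table$year[hit])
  } else {
    warning("country ", dQuote(country), " not in the emission-factor table; ",
            "assuming the worst band (> 0.3 kg CO2/kWh). ",
            "Provide a measured factor or extend the table.", call. = FALSE)
    ef <- list(value = 0.5, source = "assumed_worst",
               country = country, year = NA_integer_)
  }
  structure(ef, class = "cafri_emission_factor")
}

#' @export
print.cafri_emission_factor <- function(x, ...) {
  cat(sprintf("Emission factor: %.3f kg CO2e/kWh (%s%s%s)\n",
              x$value, x$source,
              if (!is.null(x$country)) paste0(", ", x$country) else "",
              if (!is.na(x$year)) paste0(", ", x$year) else ""))
  invisible(x)
}

#' Classify an emission factor into the scoring band
#'
#' Maps an electricity emission factor onto the `emission_factor`
#' criterion's bands: below 0.1 kg CO2/kWh earns 5 points, 0.1--0.3
#' (edges included) earns 3, and above 0.3 earns 1. A factor of exactly
#' 0.30 therefore lands in the middle, 3-point band.
#'
#' @param factor Emission factor in kg CO2e/kWh — either a positive
#'   number or a [country_emission_factor()] result.
#' @param rubric Rubric, defaults to [cafri_rubric()].
#' @return List with `label`, `points`, `criterion`.
#' @examples
#' classify_emission_band(0.30)
#' classify_emission_band(country_emission_factor("Norway"))
#' @export
classify_emission_band <- function(factor, rubric = cafri_rubric()) {
  value <- if (inherits(factor, "cafri_emission_factor")) factor$value else factor
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop("emission factor must be a single positive number (kg CO2e/kWh)",
         call. = FALSE)
  }
  classify_band(rubric, "emission_factor", value)
}
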