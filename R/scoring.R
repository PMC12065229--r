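#' Construct an answer sheet for one analytical method
#'
#' An answer sheet records, for one analytical method, the selected
#' option of each rubric criterion, plus optional metadata. Answers are
#' given by criterion id; each value is either the verbatim option label
#' (matched case-insensitively after whitespace/dash normalization) or,
#' for the numeric-band criteria, a raw measured value that is converted
#' through [classify_band()] during scoring.
#'
#' The three transport sub-criteria (`transport_distance`,
#' `shipment_size`, `eco_vehicle`) may be omitted when
#' `transport_required` is answered "No": a method whose samples never
#' travel has no transport profile to grade, and those criteria are
#' automatically awarded their best-option points.
#'
#' @param method_name Display name of the method.
#' @param answers Named list (or named character vector), names are
#'   criterion ids.
#' @param metadata Optional named list; recognised fields include
#'   `country`, `measured_emission_factor` (kg CO2e/kWh), `instruments`
#'   (character vector of technique names), `notes`.
#' @return Object of class `cafri_sheet`.
#' @examples
#' sheet <- answer_sheet("demo", list(
#'   energy_program = "Yes", instrument_power = 0.05,
#'   non_analytical_equipment = "No", sample_throughput = 40,
#'   carbon_footprint_known = "No", emission_factor = 0.05,
#'   sample_storage = "No storage was required",
#'   transport_required = "No",
#'   personnel_count = 1, automation = "automatic",
#'   waste_amount = 2, waste_disposal = "Waste disposal by the analyst",
#'   recycling = "No recycling is performed",
#'   pictogram_count = 2, organic_solvent_volume = 1, reagent_amount = 0.5))
#' @export
answer_sheet <- function(method_name, answers, metadata = list()) {
  stopifnot(is.character(method_name), length(method_name) == 1L,
            nzchar(method_name))
  if (!is.list(answers)) answers <- as.list(answers)
  if (is.null(names(answers)) || any(!nzchar(names(answers)))) {
    stop("answers must be a named list keyed by criterion id", call. = FALSE)
  }
  structure(list(method_name = method_name,
                 answers = answers,
                 metadata = as.list(metadata)),
            class = "cafri_sheet")
}

#' @export
print.cafri_sheet <- function(x, ...) {
  cat("CaFRI answer sheet:", x$method_name, "\n")
  cat(" ", length(x$answers), "answers\n")
  for (id in names(x$answers)) {
    cat(sprintf("  %-26s %s\n", id, as.character(x$answers[[id]])))
  }
  invisible(x)
}

# Resolve the transport_required answer of a sheet to "Yes"/"No"/NA.
transport_answer <- function(sheet, rubric) {
  a <- sheet$answers[["transport_required"]]
  if (is.null(a)) return(NA_character_)
  cr <- rubric$criteria[["transport_required"]]
  i <- match_option(cr, as.character(a))
  if (is.na(i)) NA_character_ else cr$options$label[i]
}

#' Validate an answer sheet against the rubric
#'
#' Checks completeness and label validity without scoring. Findings are
#' returned, not raised: an empty result means the sheet is scoreable.
#' Error-level findings are missing criteria, unknown criterion ids,
#' labels matching no option, and out-of-range numeric values; answering
#' a gated transport criterion while `transport_required` is "No" is
#' legal but flagged as a warning (the answer is ignored in scoring).
#'
#' @param sheet A [answer_sheet()] object.
#' @param rubric A [cafri_rubric()] object.
#' @return data.frame with columns `criterion`, `level` (`"error"` or
#'   `"warning"`), `message`; zero rows when the sheet is valid.
#' @export
validate_sheet <- function(sheet, rubric = cafri_rubric()) {
  stopifnot(inherits(sheet, "cafri_sheet"), inherits(rubric, "cafri_rubric"))
  findings <- list()
  add <- function(criterion, level, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(criterion = criterion, level = level, message = message,
                 stringsAsFactors = FALSE)
  }

  unknown <- setdiff(names(sheet$answers), names(rubric$criteria))
  for (id in unknown) {
    add(id, "error", paste0("unknown criterion id ", dQuote(id)))
  }

  transport <- transport_answer(sheet, rubric)
  gated_ok_absent <- identical(transport, "No")

  for (id in names(rubric$criteria)) {
    cr <- rubric$criteria[[id]]
    a <- sheet$answers[[id]]
    gated <- !is.na(cr$gated_by)
    if (is.null(a)) {
      if (gated && gated_ok_absent) next
      add(id, "error", paste0("missing answer for ", dQuote(id)))
      next
    }
    if (gated && gated_ok_absent) {
      add(id, "warning",
          paste0(dQuote(id), " answered although no transport is required; ",
                 "the answer is ignored and best points are awarded"))
      next
    }
    if (is.numeric(a)) {
      if (is.null(cr$bands)) {
        add(id, "error",
            paste0(dQuote(id), " takes no numeric value; valid answers: ",
                   paste(dQuote(cr$options$label), collapse = ", ")))
      } else {
        ok <- tryCatch({classify_band(rubric, id, a); TRUE},
                       error = function(e) FALSE)
        if (!ok) add(id, "error",
                     paste0("numeric value ", a, " is not a valid ",
                            dQuote(id), " measurement (", cr$unit, ")"))
      }
    } else if (is.na(match_option(cr, as.character(a)))) {
      add(id, "error",
          paste0("answer ", dQuote(as.character(a)), " matches no option of ",
                 dQuote(id), "; valid labels: ",
                 paste(dQuote(cr$options$label), collapse = ", ")))
    }
  }

  if (length(findings) == 0L) {
    return(data.frame(criterion = character(), level = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

# Traffic-light color of a selected option: green for the criterion's
# best option, red for its worst, yellow for anything in between.
option_color <- function(criterion, points) {
  pts <- criterion$options$points
  if (points == max(pts)) "green" else if (points == min(pts)) "red" else "yellow"
}

#' Score an answer sheet: the CaFRI assessment
#'
#' Validates the sheet, awards each criterion the points of its selected
#' option, converts raw numeric answers through the band classifier, and
#' normalizes the point total to the 0--100 CaFRI scale:
#' \deqn{\mathrm{score} = \lfloor 100 \, p / 65 \rfloor}
#' where \eqn{p} is the raw total and 65 the best achievable total over
#' all 19 criteria. Truncation (not rounding) is deliberate; it is the
#' normalization under which the published worked assessments are
#' reproduced exactly. Each criterion also receives a traffic-light
#' color: green for its best option, red for its worst, yellow between.
#'
#' When `transport_required` is "No" the gated transport criteria are
#' awarded their best-option points (green): absent transport is at
#' least as good as ideal transport, and the fixed 65-point denominator
#' is preserved.
#'
#' @param sheet A [answer_sheet()] object (or a named list of answers,
#'   which is promoted via [answer_sheet()] with name "unnamed method").
#' @param rubric A [cafri_rubric()] object.
#' @return Object of class `cafri_score`: list with `method_name`,
#'   `per_criterion` (data.frame: `id`, `category`, `label`, `points`,
#'   `max_points`, `color`, `auto_awarded`, `converted_from`),
#'   `per_category` (data.frame: `category`, `points`, `max_points`),
#'   `total_points`, `normalized_score`, `findings` (warnings), `sheet`.
#' @examples
#' s <- cafri_score(load_case_fixture(4)$sheet)
#' s$normalized_score
#' @export
cafri_score <- function(sheet, rubric = cafri_rubric()) {
  if (!inherits(sheet, "cafri_sheet") && is.list(sheet)) {
    sheet <- answer_sheet("unnamed method", sheet)
  }
  findings <- validate_sheet(sheet, rubric)
  if (any(findings$level == "error")) {
    stop("invalid answer sheet:\n  ",
         paste(findings$message[findings$level == "error"],
               collapse = "\n  "), call. = FALSE)
  }

  transport <- transport_answer(sheet, rubric)
  gate_closed <- identical(transport, "No")

  rows <- lapply(rubric$criteria, function(cr) {
    a <- sheet$answers[[cr$id]]
    auto <- FALSE
    converted <- NA_real_
    if (!is.na(cr$gated_by) && gate_closed) {
      i <- which.max(cr$options$points)
      label <- paste0(cr$options$label[i], " (auto: no transport)")
      points <- cr$options$points[i]
      auto <- TRUE
    } else if (is.numeric(a)) {
      cls <- classify_band(rubric, cr$id, a)
      label <- cls$label
      points <- cls$points
      converted <- as.numeric(a)
    } else {
      i <- match_option(cr, as.character(a))
      label <- cr$options$label[i]
      points <- cr$options$points[i]
    }
    data.frame(id = cr$id, category = cr$category, label = label,
               points = as.integer(points),
               max_points = max(cr$options$points),
               color = option_color(cr, points),
               auto_awarded = auto, converted_from = converted,
               stringsAsFactors = FALSE)
  })
  per_criterion <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  per_category <- do.call(rbind, lapply(rubric$categories$id, function(cid) {
    sub <- per_criterion[per_criterion$category == cid, ]
    data.frame(category = cid, points = sum(sub$points),
               max_points = sum(sub$max_points), stringsAsFactors = FALSE)
  }))

  total <- sum(per_criterion$points)
  structure(
    list(method_name = sheet$method_name,
         per_criterion = per_criterion,
         per_category = per_category,
         total_points = total,
         normalized_score = as.integer((total * 100L) %/%
                                         rubric$max_total_points),
         findings = findings,
         sheet = sheet),
    class = "cafri_score"
  )
}

#' @export
print.cafri_score <- function(x, ...) {
  cat("CaFRI assessment:", x$method_name, "\n")
  cat(sprintf("  Score: %d / 100  (%d of %d raw points)\n",
              x$normalized_score, x$total_points,
              sum(x$per_criterion$max_points)))
  reds <- x$per_criterion$id[x$per_criterion$color == "red"]
  if (length(reds)) {
    cat("  Red zones:", paste(reds, collapse = ", "), "\n")
  } else {
    cat("  Red zones: none\n")
  }
  invisible(x)
}

#' @export
summary.cafri_score <- function(object, ...) {
  cat("CaFRI assessment:", object$method_name, "\n\n")
  cat("Per category:\n")
  pc <- object$per_category
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-18s %2d / %2d\n", pc$category[i], pc$points[i],
                pc$max_points[i]))
  }
  cat(sprintf("\nTotal: %d / 65 raw points -> CaFRI score %d / 100\n",
              object$total_points, object$normalized_score))
  colors <- table(factor(object$per_criterion$color,
                         levels = c("green", "yellow", "red")))
  cat(sprintf("Zones: %d green, %d yellow, %d red\n",
              colors["green"], colors["yellow"], colors["red"]))
  invisible(object)
}

#' @export
as.data.frame.cafri_score <- function(x, ...) {
  x$per_criterion
}

#' Compare several scored methods
#'
#' Scores each sheet and tabulates them side by side, ranked by CaFRI
#' score (descending; ties broken alphabetically by method name). The
#' count of red zones is included: the red criteria are where an
#' assessment points the analyst for improvement.
#'
#' @param sheets List of at least two [answer_sheet()] objects.
#' @param rubric A [cafri_rubric()] object.
#' @return data.frame of class `cafri_comparison` with columns
#'   `method_name`, `total_points`, `normalized_score`, `red_zones`.
#' @export
compare_sheets <- function(sheets, rubric = cafri_rubric()) {
  if (!is.list(sheets) || length(sheets) < 2L) {
    stop("compare_sheets() needs a list of at least two answer sheets",
         call. = FALSE)
  }
  scored <- lapply(sheets, cafri_score, rubric = rubric)
  tab <- do.call(rbind, lapply(scored, function(s) {
    data.frame(method_name = s$method_name,
               total_points = s$total_points,
               normalized_score = s$normalized_score,
               red_zones = sum(s$per_criterion$color == "red"),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$normalized_score, tab$method_name), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("cafri_comparison", class(tab))
  tab
}

#' @export
print.cafri_comparison <- function(x, ...) {
  cat("CaFRI comparison (best first):\n")
  print.data.frame(x)
  invisible(x)
}
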