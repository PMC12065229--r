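#' Read an answer sheet from YAML or JSON
#'
#' Accepts the published answer-sheet layout: top-level `method_name`,
#' `answers` (criterion id -> option label or raw numeric value for the
#' banded criteria) and optional `metadata`. The format is inferred from
#' the file extension (`.yaml`/`.yml` or `.json`) unless given. Unquoted
#' YAML `yes`/`no` values are mapped onto the rubric's "Yes"/"No"
#' labels. A schema describing the layout ships at
#' `system.file("extdata", "answer_sheet_schema.json", package = "cafri")`.
#'
#' @param path File path.
#' @param format `"auto"`, `"yaml"` or `"json"`.
#' @return A [answer_sheet()] object.
#' @export
read_answer_sheet <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  raw <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$answers)) {
    stop("answer-sheet file ", dQuote(path), " has no 'answers' block",
         call. = FALSE)
  }
  answers <- lapply(raw$answers, yes_no_from_logical)
  answer_sheet(
    method_name = if (is.null(raw$method_name)) "unnamed method"
                  else raw$method_name,
    answers = answers,
    metadata = if (is.null(raw$metadata)) list() else raw$metadata)
}

#' Write an answer sheet to YAML or JSON
#'
#' JSON is the canonical interchange output; YAML is convenient to edit.
#'
#' @param sheet A [answer_sheet()] object.
#' @param path Destination file.
#' @param format `"auto"` (from extension), `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_answer_sheet <- function(sheet, path, format = c("auto", "yaml", "json")) {
  stopifnot(inherits(sheet, "cafri_sheet"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  doc <- list(method_name = sheet$method_name,
              answers = sheet$answers,
              metadata = sheet$metadata)
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    # quote strings so "Yes"/"No" survive the YAML boolean trap
    yaml::write_yaml(doc, path,
                     handlers = list(character = function(x)
                       structure(x, quoted = TRUE)))
  }
  invisible(path)
}

#' Export a score breakdown as JSON
#'
#' Full per-criterion and per-category detail plus totals, suitable for
#' archiving alongside the pictogram.
#'
#' @param score A [cafri_score()] object.
#' @param path Optional destination; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
score_to_json <- function(score, path = NULL) {
  stopifnot(inherits(score, "cafri_score"))
  doc <- list(method_name = score$method_name,
              normalized_score = score$normalized_score,
              total_points = score$total_points,
              max_total_points = sum(score$per_criterion$max_points),
              per_category = score$per_category,
              per_criterion = score$per_criterion)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Export a score breakdown as flat CSV
#'
#' One row per criterion: `id`, `category`, `label`, `points`,
#' `max_points`, `color`.
#'
#' @param score A [cafri_score()] object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
score_to_csv <- function(score, path) {
  stopifnot(inherits(score, "cafri_score"))
  cols <- c("id", "category", "label", "points", "max_points", "color")
  utils::write.csv(score$per_criterion[, cols], path, row.names = FALSE)
  invisible(path)
}
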