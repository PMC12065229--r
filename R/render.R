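# Fixed traffic-light palette; hex values frozen so SVG output is
# byte-stable across runs and machines.
cafri_palette <- c(red = "#d62728", yellow = "#f2c200", green = "#2ca02c")

# Zone layout of the foot pictogram. Original layout (the published
# concept fixes only the idea of a foot with colored criterion zones):
# toes = recycling + reagents/solvents, ball = personnel + waste,
# arch = storage + transportation (with the score numeral in the
# middle), heel = energy + CO2 emission.
pictogram_layout <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
id                       region cx  cy
recycling                toes   75  100
pictogram_count          toes   120 82
organic_solvent_volume   toes   165 75
reagent_amount           toes   210 85
personnel_count          ball   95  160
automation               ball   150 148
waste_amount             ball   205 160
waste_disposal           ball   150 200
sample_storage           arch   95  250
transport_required       arch   205 250
transport_distance       arch   90  320
shipment_size            arch   210 320
eco_vehicle              arch   150 360
energy_program           heel   105 400
instrument_power         heel   195 400
non_analytical_equipment heel   95  445
sample_throughput        heel   205 445
carbon_footprint_known   heel   125 485
emission_factor          heel   175 485
")
}

check_complete_score <- function(score) {
  if (!inherits(score, "cafri_score") ||
      is.null(score$per_criterion) ||
      nrow(score$per_criterion) != 19L ||
      anyNA(score$per_criterion$color) ||
      !all(score$per_criterion$color %in% names(cafri_palette))) {
    stop("a complete cafri_score with all 19 criterion colors is required",
         call. = FALSE)
  }
  invisible(score)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the foot-shaped result pictogram as SVG
#'
#' Draws the CaFRI result as a human-foot silhouette with 19 colored
#' zones (one per criterion, grouped by category region), the normalized
#' score as a central numeral, and a numbered legend. Zone elements
#' carry machine-readable ids (`zone-<criterion id>`) and their fill is
#' the criterion's traffic-light color, so downstream tools and tests
#' can interrogate the figure without image processing. Output is a pure
#' function of the score: identical input yields identical bytes.
#'
#' @param score A complete [cafri_score()] object.
#' @param path Optional file to write the SVG to.
#' @return The SVG document as a single character string (class
#'   `cafri_pictogram`); invisibly when written to `path`.
#' @examples
#' svg <- render_pictogram(cafri_score(load_case_fixture(1)$sheet))
#' @export
render_pictogram <- function(score, path = NULL) {
  check_complete_score(score)
  lay <- pictogram_layout()
  pc <- score$per_criterion
  pc <- pc[match(lay$id, pc$id), ]

  zone <- character(nrow(lay))
  legend <- character(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    fill <- cafri_palette[[pc$color[i]]]
    zone[i] <- paste0(
      sprintf('  <circle id="zone-%s" class="zone zone-%s" cx="%d" cy="%d" r="17" fill="%s" stroke="#333333" stroke-width="1.5"/>\n',
              lay$id[i], pc$color[i], lay$cx[i], lay$cy[i], fill),
      sprintf('  <text x="%d" y="%d" text-anchor="middle" font-size="13" font-family="Helvetica, Arial, sans-serif" fill="#ffffff" font-weight="bold">%d</text>',
              lay$cx[i], lay$cy[i] + 5L, i))
    legend[i] <- paste0(
      sprintf('  <rect x="310" y="%d" width="12" height="12" fill="%s" stroke="#333333" stroke-width="0.5"/>\n',
              46 + 24 * (i - 1L), fill),
      sprintf('  <text x="328" y="%d" font-size="12" font-family="Helvetica, Arial, sans-serif" fill="#222222">%d. %s (%d/%d)</text>',
              56 + 24 * (i - 1L), i, xml_escape(lay$id[i]),
              pc$points[i], pc$max_points[i]))
  }

  toes <- "
  <circle cx=\"70\" cy=\"38\" r=\"15\" fill=\"#f5f0e8\" stroke=\"#777777\" stroke-width=\"1.5\"/>
  <circle cx=\"110\" cy=\"28\" r=\"12\" fill=\"#f5f0e8\" stroke=\"#777777\" stroke-width=\"1.5\"/>
  <circle cx=\"150\" cy=\"24\" r=\"11\" fill=\"#f5f0e8\" stroke=\"#777777\" stroke-width=\"1.5\"/>
  <circle cx=\"190\" cy=\"28\" r=\"10\" fill=\"#f5f0e8\" stroke=\"#777777\" stroke-width=\"1.5\"/>
  <circle cx=\"226\" cy=\"38\" r=\"9\" fill=\"#f5f0e8\" stroke=\"#777777\" stroke-width=\"1.5\"/>"
  outline <- paste0(
    '  <path id="sole" d="M 150 515 C 90 515 60 470 62 420 C 64 370 85 340 ',
    '80 290 C 75 240 60 200 65 150 C 70 100 100 60 150 58 C 200 60 232 100 ',
    '236 150 C 240 200 228 240 222 290 C 216 340 236 370 238 420 C 240 470 ',
    '210 515 150 515 Z" fill="#f5f0e8" stroke="#777777" stroke-width="2"/>')

  svg <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="580" height="540" viewBox="0 0 580 540">\n',
    '<rect width="580" height="540" fill="#ffffff"/>\n',
    sprintf('<text x="310" y="24" font-size="15" font-family="Helvetica, Arial, sans-serif" font-weight="bold" fill="#222222">%s</text>\n',
            xml_escape(score$method_name)),
    '<g id="foot">\n', toes, "\n", outline, "\n</g>\n",
    '<g id="zones">\n', paste(zone, collapse = "\n"), "\n</g>\n",
    sprintf('<text id="score" x="150" y="300" text-anchor="middle" font-size="44" font-family="Helvetica, Arial, sans-serif" font-weight="bold" fill="#222222">%d</text>\n',
            score$normalized_score),
    '<g id="legend">\n', paste(legend, collapse = "\n"), "\n</g>\n",
    "</svg>\n")
  class(svg) <- c("cafri_pictogram", "character")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(svg), con)
    return(invisible(svg))
  }
  svg
}

#' @export
print.cafri_pictogram <- function(x, ...) {
  cat("CaFRI foot pictogram (SVG,", nchar(x), "bytes, 19 zones).\n")
  cat("Write it with writeLines(x, \"pictogram.svg\").\n")
  invisible(x)
}

#' Render a human-readable assessment report
#'
#' Produces a per-category score table, the full per-criterion detail,
#' and improvement hints: the red zones are the criteria where the
#' assessed method loses the most ground, and tracking them is how a
#' method's footprint performance is improved. The HTML variant embeds
#' the foot pictogram.
#'
#' @param score A complete [cafri_score()] object.
#' @param format `"markdown"` or `"html"`.
#' @return The report as a single character string.
#' @export
render_report <- function(score, format = c("markdown", "html")) {
  format <- match.arg(format)
  check_complete_score(score)
  pc <- score$per_criterion
  cat_tab <- score$per_category

  lines <- c(
    paste0("# CaFRI assessment: ", score$method_name),
    "",
    sprintf("**CaFRI score: %d / 100** (%d of 65 raw points)",
            score$normalized_score, score$total_points),
    "",
    "## Category summary",
    "",
    "| Category | Points | Max |",
    "|---|---:|---:|",
    sprintf("| %s | %d | %d |", cat_tab$category, cat_tab$points,
            cat_tab$max_points),
    "",
    "## Criteria",
    "",
    "| # | Criterion | Answer | Points | Max | Color |",
    "|---:|---|---|---:|---:|---|",
    sprintf("| %d | %s | %s | %d | %d | %s |", seq_len(nrow(pc)), pc$id,
            pc$label, pc$points, pc$max_points, pc$color),
    "",
    "## Improvement hints")
  reds <- pc[pc$color == "red", ]
  if (nrow(reds) == 0L) {
    lines <- c(lines, "", "No red zones: every criterion already takes its best or an intermediate option.")
  } else {
    lines <- c(lines, "",
               "Red zones to track (worst option selected):", "",
               sprintf("- **%s** — currently \"%s\" (%d/%d points)",
                       reds$id, reds$label, reds$points, reds$max_points))
  }
  md <- paste(lines, collapse = "\n")
  if (format == "markdown") return(md)

  html_tables <- md_to_html_blocks(lines)
  paste0("<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
         "<title>", xml_escape(score$method_name), "</title>\n",
         "<style>body{font-family:Helvetica,Arial,sans-serif;max-width:60em;margin:2em auto;}table{border-collapse:collapse;}td,th{border:1px solid #999;padding:4px 8px;}</style>\n",
         "</head>\n<body>\n", html_tables,
         "\n<h2>Pictogram</h2>\n",
         sub('^<\\?xml[^>]*\\?>\n', "", unclass(render_pictogram(score))),
         "</body>\n</html>\n")
}

# Minimal markdown-to-HTML conversion for the report's own structure
# (headings, pipe tables, bullet lists, bold). Not a general converter.
md_to_html_blocks <- function(lines) {
  out <- character(0)
  in_table <- FALSE
  for (ln in lines) {
    if (grepl("^\\|", ln)) {
      cells <- strsplit(sub("\\|$", "", sub("^\\|", "", ln)), "|",
                        fixed = TRUE)[[1]]
      cells <- trimws(cells)
      if (all(grepl("^:?-+:?$", cells))) next
      if (!in_table) { out <- c(out, "<table>"); in_table <- TRUE }
      out <- c(out, paste0("<tr>", paste0("<td>", xml_escape(cells), "</td>",
                                          collapse = ""), "</tr>"))
      next
    }
    if (in_table) { out <- c(out, "</table>"); in_table <- FALSE }
    ln <- gsub("\\*\\*([^*]+)\\*\\*", "<strong>\\1</strong>", ln)
    if (grepl("^# ", ln)) out <- c(out, paste0("<h1>", sub("^# ", "", ln), "</h1>"))
    else if (grepl("^## ", ln)) out <- c(out, paste0("<h2>", sub("^## ", "", ln), "</h2>"))
    else if (grepl("^- ", ln)) out <- c(out, paste0("<p>", sub("^- ", "&bull; ", ln), "</p>"))
    else if (nzchar(ln)) out <- c(out, paste0("<p>", ln, "</p>"))
  }
  if (in_table) out <- c(out, "</table>")
  paste(out, collapse = "\n")
}

#' Plot a CaFRI assessment as the foot pictogram
#'
#' Base-graphics rendition of the foot pictogram: silhouette, 19 colored
#' criterion zones and the central score numeral. For a vector file use
#' [render_pictogram()], which produces the canonical SVG.
#'
#' @param x A complete [cafri_score()] object.
#' @param ... Ignored.
#' @export
plot.cafri_score <- function(x, ...) {
  check_complete_score(x)
  lay <- pictogram_layout()
  pc <- x$per_criterion[match(lay$id, x$per_criterion$id), ]

  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 300), ylim = c(540, 0), asp = 1)
  graphics::title(main = sprintf("%s — CaFRI %d", x$method_name,
                                 x$normalized_score))
  # sole outline through the path's anchor points, closed spline
  bx <- c(150, 90, 62, 80, 65, 150, 236, 222, 238, 210)
  by <- c(515, 500, 420, 290, 150, 58, 150, 290, 420, 500)
  graphics::xspline(bx, by, shape = 1, open = FALSE, border = "#777777",
                    col = "#f5f0e8", lwd = 2)
  graphics::symbols(c(70, 110, 150, 190, 226), c(38, 28, 24, 28, 38),
                    circles = c(15, 12, 11, 10, 9), inches = FALSE,
                    add = TRUE, bg = "#f5f0e8", fg = "#777777")
  graphics::symbols(lay$cx, lay$cy, circles = rep(17, nrow(lay)),
                    inches = FALSE, add = TRUE,
                    bg = cafri_palette[pc$color], fg = "#333333")
  graphics::text(lay$cx, lay$cy, labels = seq_len(nrow(lay)),
                 col = "white", cex = 0.8, font = 2)
  graphics::text(150, 300, labels = x$normalized_score, cex = 2.4, font = 2)
  invisible(x)
}
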