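r <- rubric_fixture

test_that("ideal and worst-case sheets hit the scale extremes", {
  best <- cafri_score(all_best_sheet(), r)
  expect_equal(best$total_points, 65L)
  expect_equal(best$normalized_score, 100L)
  expect_true(all(best$per_criterion$color == "green"))

  worst <- cafri_score(all_worst_sheet(), r)
  expect_equal(worst$total_points, 19L)
  expect_equal(worst$normalized_score, 29L)
  expect_true(all(worst$per_criterion$color == "red"))
})

test_that("validation findings pinpoint missing and malformed answers", {
  fx <- load_case_fixture(4)
  expect_equal(nrow(validate_sheet(fx$sheet, r)), 0L)

  incomplete <- fx$sheet
  incomplete$answers$waste_disposal <- NULL
  f <- validate_sheet(incomplete, r)
  expect_equal(nrow(f), 1L)
  expect_equal(f$criterion, "waste_disposal")
  expect_equal(f$level, "error")

  bad <- fx$sheet
  bad$answers$automation <- "robotic"
  f <- validate_sheet(bad, r)
  expect_equal(nrow(f), 1L)
  expect_match(f$message, "automatic")
  expect_match(f$message, "semiautomatic")
  expect_match(f$message, "manual")

  unknown <- fx$sheet
  unknown$answers$coffee_consumption <- "high"
  f <- validate_sheet(unknown, r)
  expect_equal(f$criterion, "coffee_consumption")
  expect_equal(f$level, "error")

  expect_error(cafri_score(bad, r), "invalid answer sheet")
})

test_that("label matching tolerates case, whitespace and dash variants", {
  fx <- load_case_fixture(1)
  s0 <- cafri_score(fx$sheet, r)
  alt <- fx$sheet
  alt$answers$instrument_power <- "  > 1.5 KW "
  alt$answers$personnel_count <- "2 - 3 persons"
  alt$answers$emission_factor <- "> 0.3 kg CO_2/kWh"
  s1 <- cafri_score(alt, r)
  expect_equal(s1$total_points, s0$total_points)
})

test_that("the transport gate awards best points and flags ignored answers", {
  base <- all_worst_sheet()
  base$answers$transport_required <- "No"
  base$answers$transport_distance <- NULL
  base$answers$shipment_size <- NULL
  base$answers$eco_vehicle <- NULL
  s <- cafri_score(base, r)
  gated <- s$per_criterion[s$per_criterion$id %in%
                             c("transport_distance", "shipment_size",
                               "eco_vehicle"), ]
  expect_equal(gated$points, c(3L, 4L, 2L))
  expect_true(all(gated$color == "green"))
  expect_true(all(gated$auto_awarded))
  # worst everywhere else (16 criteria) + No transport (2) + gated best (9)
  expect_equal(s$total_points, 16L - 1L + 2L + 9L)

  answered <- base
  answered$answers$eco_vehicle <- "No"
  f <- validate_sheet(answered, r)
  expect_equal(f$level, "warning")
  expect_equal(f$criterion, "eco_vehicle")
  s2 <- cafri_score(answered, r)
  expect_equal(s2$total_points, s$total_points)  # answer ignored

  gated_missing <- all_worst_sheet()
  gated_missing$answers$shipment_size <- NULL   # transport is "Yes" here
  f <- validate_sheet(gated_missing, r)
  expect_equal(f$level, "error")
})

test_that("colors follow best/worst/interior option selection", {
  sheet <- all_best_sheet()
  sheet$answers$emission_factor <- "> 0.3 kg CO2/kWh"
  sheet$answers$pictogram_count <- "4–6"
  s <- cafri_score(sheet, r)
  pc <- s$per_criterion
  expect_equal(pc$color[pc$id == "emission_factor"], "red")
  expect_equal(pc$color[pc$id == "pictogram_count"], "yellow")
  expect_equal(pc$color[pc$id == "transport_required"], "green")
  # two-option criteria can only be green or red
  sheet$answers$energy_program <- "No"
  pc <- cafri_score(sheet, r)$per_criterion
  expect_equal(pc$color[pc$id == "energy_program"], "red")
})

test_that("raw numeric answers are classified through the band rules", {
  sheet <- all_best_sheet()
  sheet$answers$emission_factor <- 0.30
  s <- cafri_score(sheet, r)
  row <- s$per_criterion[s$per_criterion$id == "emission_factor", ]
  expect_equal(row$points, 3L)
  expect_equal(row$label, "0.1–0.3 kg CO2/kWh")
  expect_equal(row$converted_from, 0.30)
  expect_equal(s$total_points, 63L)
})

test_that("answer insertion order never affects the result", {
  fx <- load_case_fixture(3)
  s0 <- cafri_score(fx$sheet, r)
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- fx$sheet
    shuffled$answers <- shuffled$answers[sample(length(shuffled$answers))]
    s1 <- cafri_score(shuffled, r)
    expect_equal(s1$per_criterion, s0$per_criterion)
    expect_equal(s1$normalized_score, s0$normalized_score)
  }
})

test_that("per-category subtotals partition the total", {
  for (seed in 1:25) {
    s <- cafri_score(generate_random_sheet(seed, r), r)
    expect_equal(sum(s$per_category$points), s$total_points)
    expect_equal(sum(s$per_category$max_points), 65L)
    expect_true(s$total_points >= 19L && s$total_points <= 65L)
    expect_true(s$normalized_score >= 29L && s$normalized_score <= 100L)
  }
})

test_that("upgrading any single answer strictly increases the score", {
  for (seed in 1:20) {
    sheet <- generate_random_sheet(seed, r)
    s0 <- cafri_score(sheet, r)
    for (id in names(sheet$answers)) {
      cr <- r$criteria[[id]]
      if (id == "transport_required") next  # flipping alters the gate
      i <- match(sheet$answers[[id]], cr$options$label)
      if (i == 1L) next
      up <- sheet
      up$answers[[id]] <- cr$options$label[i - 1L]
      s1 <- cafri_score(up, r)
      expect_gt(s1$normalized_score, s0$normalized_score)
    }
  }
})

test_that("comparison table ranks by score with alphabetical tie-break", {
  c1 <- load_case_fixture(1)$sheet
  c4 <- load_case_fixture(4)$sheet
  tab <- compare_sheets(list(c1, c4), r)
  expect_equal(tab$normalized_score, c(81L, 63L))
  expect_match(tab$method_name[1], "case 4")
  expect_true(all(c("total_points", "red_zones") %in% names(tab)))

  twin_a <- c1; twin_a$method_name <- "zeta assay"
  twin_b <- c1; twin_b$method_name <- "alpha assay"
  tie <- compare_sheets(list(twin_a, twin_b), r)
  expect_equal(tie$method_name, c("alpha assay", "zeta assay"))

  expect_error(compare_sheets(list(c1), r), "at least two")
})

test_that("normalization bands mirror the published interpretation", {
  # raw totals 33-48 land in scores 50-74; >= 49 lands at >= 75
  for (p in 19:65) {
    s <- cafri_score(make_sheet_with_total(p, r), r)
    expect_equal(s$total_points, p)
    expect_equal(s$normalized_score, (p * 100L) %/% 65L)
    in_mid <- s$normalized_score >= 50L && s$normalized_score <= 74L
    expect_equal(in_mid, p >= 33L && p <= 48L, info = p)
    expect_equal(s$normalized_score >= 75L, p >= 49L, info = p)
  }
})
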