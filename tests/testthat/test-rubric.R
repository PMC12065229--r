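test_that("rubric has 19 criteria in 8 categories with the published layout", {
  r <- rubric_fixture
  expect_s3_class(r, "cafri_rubric")
  expect_length(r$criteria, 19L)
  expect_equal(nrow(r$categories), 8L)

  dist <- table(vapply(r$criteria, `[[`, "", "category"))
  expect_equal(
    as.integer(dist[c("ENERGY", "CO2_EMISSION", "STORAGE", "TRANSPORTATION",
                      "PERSONNEL", "WASTE", "RECYCLING", "REAGENTS_SOLVENTS")]),
    c(4L, 2L, 1L, 4L, 2L, 2L, 1L, 3L))

  gated <- names(Filter(function(cr) !is.na(cr$gated_by), r$criteria))
  expect_setequal(gated, c("transport_distance", "shipment_size", "eco_vehicle"))
  expect_true(all(vapply(r$criteria[gated], `[[`, "", "gated_by") ==
                    "transport_required"))
})

test_that("best- and worst-option totals enumerate to 65 and 19", {
  r <- rubric_fixture
  best <- vapply(r$criteria, function(cr) max(cr$options$points), 0L)
  worst <- vapply(r$criteria, function(cr) min(cr$options$points), 0L)
  expect_equal(sum(best), 65L)
  expect_equal(sum(worst), 19L)
  expect_equal(r$max_total_points, 65L)
  expect_equal(r$min_total_points, 19L)
})

test_that("every criterion's options decrease strictly with unique labels in [1,5]", {
  for (cr in rubric_fixture$criteria) {
    pts <- cr$options$points
    expect_true(all(diff(pts) < 0), info = cr$id)
    expect_true(all(pts >= 1L & pts <= 5L), info = cr$id)
    expect_equal(anyDuplicated(cr$options$label), 0L, info = cr$id)
    expect_equal(min(pts), 1L, info = cr$id)
  }
})

test_that("option-shape facts match the published table", {
  r <- rubric_fixture
  n_opts <- vapply(r$criteria, function(cr) nrow(cr$options), 0L)
  four_opt <- names(n_opts)[n_opts == 4L]
  expect_setequal(four_opt,
                  c("shipment_size", "personnel_count", "pictogram_count"))
  for (id in four_opt) {
    expect_equal(r$criteria[[id]]$options$points, c(4L, 3L, 2L, 1L), info = id)
  }
  five_best <- names(Filter(function(cr) max(cr$options$points) == 5L,
                            r$criteria))
  expect_setequal(five_best, c("instrument_power", "emission_factor"))

  ef <- find_criterion(r, "emission_factor")
  expect_equal(ef$options$points, c(5L, 3L, 1L))
  expect_equal(ef$options$label,
               c("< 0.1 kg CO2/kWh", "0.1–0.3 kg CO2/kWh",
                 "> 0.3 kg CO2/kWh"))
})

test_that("find_criterion retrieves by id and rejects unknown ids", {
  r <- rubric_fixture
  ip <- find_criterion(r, "instrument_power")
  expect_equal(nrow(ip$options), 3L)
  expect_equal(max(ip$options$points), 5L)

  tr <- find_criterion(r, "transport_required")
  expect_equal(tr$options$points, c(2L, 1L))
  expect_equal(tr$options$label, c("No", "Yes"))

  expect_error(find_criterion(r, "bogus"), "bogus")
  expect_error(find_criterion(r, "bogus"), "transport_required") # lists valid ids
})

test_that("rubric JSON serialization round-trips losslessly", {
  r <- rubric_fixture
  js <- rubric_to_json(r)
  back <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(back, 19L)
  for (rec in back) {
    cr <- r$criteria[[rec$id]]
    expect_equal(rec$category, cr$category)
    expect_equal(rec$question, cr$question)
    expect_equal(vapply(rec$options, `[[`, "", "label"), cr$options$label)
    expect_equal(vapply(rec$options, function(o) as.integer(o$points), 0L),
                 cr$options$points)
    if (is.na(cr$gated_by)) expect_null(rec$gated_by)
    else expect_equal(rec$gated_by, cr$gated_by)
  }
  # file round-trip too
  tmp <- withr::local_tempfile(fileext = ".json")
  rubric_to_json(r, tmp)
  expect_equal(jsonlite::fromJSON(tmp, simplifyVector = FALSE), back)
})

test_that("classify_band honors the inclusive-better-band edge rule", {
  r <- rubric_fixture
  expect_equal(classify_band(r, "sample_throughput", 30)$points, 2L)
  expect_equal(classify_band(r, "sample_throughput", 31)$points, 3L)
  expect_equal(classify_band(r, "sample_throughput", 10)$points, 2L)
  expect_equal(classify_band(r, "sample_throughput", 9.9)$points, 1L)
  expect_equal(classify_band(r, "shipment_size", 100)$points, 3L)
  expect_equal(classify_band(r, "pictogram_count", 3)$points, 4L)
  expect_equal(classify_band(r, "pictogram_count", 9)$points, 2L)
  expect_error(classify_band(r, "automation", 2), "no numeric bands")
  expect_error(classify_band(r, "waste_amount", -1), "non-negative")
})
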