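make_raw <- function(signals, doses, experiment = "E1", endpoint = "ATP",
                     cell_type = "A549", particle = "NP") {
  data.frame(experiment_id = experiment, cell_type = cell_type,
             particle = particle, dose = doses, endpoint = endpoint,
             role = "cells", replicate = seq_along(signals),
             signal = signals, stringsAsFactors = FALSE)
}

test_that("blank correction subtracts, floors at zero and warns", {
  expect_equal(blank_correct(120, 20), 100)
  expect_equal(blank_correct(100, 0), 100)
  expect_warning(out <- blank_correct(10, 25), "floored")
  expect_equal(out, 0)
  expect_error(blank_correct(c(1, 2), c(1, 2, 3)), "keying")
})

test_that("fold effects normalize to the zero-dose grand mean per experiment", {
  raw <- make_raw(c(100, 110, 90, 50), c(0, 0, 0, 10))
  fe <- suppressMessages(compute_fold_effect(raw))
  expect_equal(fe$fe[4], 0.5)
  expect_equal(mean(fe$fe[fe$dose == 0]), 1)

  # two experiments with different control levels normalize independently
  raw2 <- rbind(make_raw(c(100, 100, 80), c(0, 0, 20), experiment = "E1"),
                make_raw(c(200, 200, 80), c(0, 0, 20), experiment = "E2"))
  fe2 <- suppressMessages(compute_fold_effect(raw2))
  expect_equal(fe2$fe[fe2$experiment_id == "E1" & fe2$dose == 20], 0.8)
  expect_equal(fe2$fe[fe2$experiment_id == "E2" & fe2$dose == 20], 0.4)
})

test_that("normalization strata separate endpoints and cell types", {
  raw <- rbind(make_raw(c(100, 50), c(0, 10), endpoint = "ATP"),
               make_raw(c(1000, 900), c(0, 10), endpoint = "CTB"))
  fe <- suppressMessages(compute_fold_effect(raw))
  expect_equal(fe$fe[fe$endpoint == "ATP" & fe$dose == 10], 0.5)
  expect_equal(fe$fe[fe$endpoint == "CTB" & fe$dose == 10], 0.9)
})

test_that("missing zero-dose controls and degenerate control means error", {
  raw <- make_raw(c(100, 50), c(5, 10))
  expect_error(suppressMessages(compute_fold_effect(raw)), "zero-dose")

  raw0 <- make_raw(c(0, 0, 50), c(0, 0, 10))
  expect_error(suppressMessages(compute_fold_effect(raw0)),
               "grand mean <= 0")
})

test_that("fold effects are invariant to rescaling an experiment", {
  raw <- make_raw(c(100, 110, 90, 50, 30), c(0, 0, 0, 10, 40))
  fe1 <- suppressMessages(compute_fold_effect(raw))
  raw$signal <- raw$signal * 7.3
  fe2 <- suppressMessages(compute_fold_effect(raw))
  expect_equal(fe1$fe, fe2$fe)
})

test_that("matched no-cells blanks are subtracted before normalization", {
  raw <- make_raw(c(110, 120, 60), c(0, 0, 10))
  blanks <- data.frame(experiment_id = "E1", cell_type = "A549",
                       particle = "NP", dose = c(0, 10), endpoint = "ATP",
                       role = "no_cells", replicate = 1,
                       signal = c(15, 10), stringsAsFactors = FALSE)
  fe <- compute_fold_effect(rbind(raw, blanks))
  # controls: (110-15, 120-15) -> mean 100; dosed: 60-10 = 50
  expect_equal(fe$fe[fe$dose == 10], 0.5)
})

test_that("unmatched blanks pass signals through with a notice", {
  raw <- make_raw(c(100, 100, 50), c(0, 0, 10))
  blanks <- data.frame(experiment_id = "E9", cell_type = "A549",
                       particle = "NP", dose = 0, endpoint = "ATP",
                       role = "no_cells", replicate = 1, signal = 5,
                       stringsAsFactors = FALSE)
  expect_message(fe <- compute_fold_effect(rbind(raw, blanks)),
                 "passed through")
  expect_equal(fe$fe[fe$dose == 10], 0.5)
})

test_that("percent LDH is linear in released signal and stable to duplicated totals", {
  expect_equal(pct_ldh(0, c(200, 200)), 0)
  expect_equal(pct_ldh(50, 200), 25)
  expect_equal(pct_ldh(200, c(190, 210)), 100)
  expect_equal(pct_ldh(2 * 37, c(200, 200)), 2 * pct_ldh(37, c(200, 200)))
  expect_equal(pct_ldh(80, rep(c(190, 210), 4)), pct_ldh(80, c(190, 210)))
  expect_error(pct_ldh(10, numeric(0)), "nonempty")
  expect_error(pct_ldh(10, c(-5, 1)), "positive")
})

test_that("table-level %LDH uses lysed controls of the same experiment", {
  raw <- make_raw(c(10, 10, 40), c(0, 0, 30), endpoint = "LDH")
  lysed <- data.frame(experiment_id = "E1", cell_type = "A549",
                      particle = "none", dose = 0, endpoint = "LDH",
                      role = "lysed_control", replicate = 1:2,
                      signal = c(190, 210), stringsAsFactors = FALSE)
  out <- compute_pct_ldh(rbind(raw, lysed))
  expect_equal(out$pct_ldh, c(5, 5, 20))
  expect_error(compute_pct_ldh(raw), "lysed_control")
})

test_that("validation rejects malformed assay tables", {
  raw <- make_raw(c(100, 50), c(0, 10))
  expect_error(validate_assay_table(raw[, -4]), "missing columns")
  bad <- raw; bad$dose[1] <- -1
  expect_error(validate_assay_table(bad), "dose")
  bad <- raw; bad$signal[1] <- Inf
  expect_error(validate_assay_table(bad), "finite")
  bad <- raw; bad$role[1] <- "mystery"
  expect_error(validate_assay_table(bad), "role")
})
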