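med_catalog <- data.frame(
  drug_id = c("DX1", "DX2"),
  ingredient = c("testdrug_mass", "testdrug_act"),
  amount = c(5, 500), amount_unit = c("mg", "U"),
  volume_ml = c(50, 50), standard_unit = c("mg/h", "U/h"),
  stringsAsFactors = FALSE
)

med_raw <- function(doc_format, value, unit, start, end = NA,
                    drug_id = "DX1") {
  data.frame(record_id = "M1", case_id = "C1", drug_id = drug_id,
             doc_format = doc_format, value = value, unit = unit,
             start_ts = start, end_ts = end, stringsAsFactors = FALSE)
}

test_that("concentration is ingredient amount over diluent volume", {
  expect_equal(reconstruct_concentration(5, 50), 0.1)
  expect_equal(reconstruct_concentration(500, 50), 10)
  expect_equal(reconstruct_concentration(0, 50), 0)  # placebo mixture
  expect_error(reconstruct_concentration(5, 0), class = "pdms_value_error")
  expect_error(reconstruct_concentration(-1, 50), class = "pdms_value_error")
})

test_that("the three documentation formats standardize correctly", {
  # rate: 6 mL/h of a 0.1 mg/mL mixture -> 0.6 mg/h infusion
  ev <- standardize_record(med_raw("rate", 6, "mL/h", "2024-02-01T10:00:00Z",
                                   "2024-02-01T14:00:00Z"), med_catalog)
  expect_equal(ev$kind, "infusion")
  expect_equal(ev$value, 0.6)
  expect_equal(ev$unit, "mg/h")
  expect_equal(ev$start_ts, "2024-02-01T11:00:00+01:00")
  # volume: 30 mL over 2 h of 0.1 mg/mL -> 1.5 mg/h
  ev2 <- standardize_record(med_raw("volume", 30, "mL", "2024-02-01T10:00:00Z",
                                    "2024-02-01T12:00:00Z"), med_catalog)
  expect_equal(ev2$value, 1.5)
  expect_equal(ev2$unit, "mg/h")
  # dose: 500 ug -> 0.5 mg bolus at the administration instant
  ev3 <- standardize_record(med_raw("dose", 500, "ug", "2024-02-01T10:00:00Z"),
                            med_catalog)
  expect_equal(ev3$kind, "bolus")
  expect_equal(ev3$value, 0.5)
  expect_equal(ev3$unit, "mg")
  expect_equal(ev3$end_ts, ev3$start_ts)
  # activity drugs standardize in U, never mg
  ev4 <- standardize_record(med_raw("rate", 2, "mL/h", "2024-02-01T10:00:00Z",
                                    "2024-02-01T14:00:00Z", drug_id = "DX2"),
                            med_catalog)
  expect_equal(ev4$value, 20)
  expect_equal(ev4$unit, "U/h")
})

test_that("unresolvable records are routed to failures, never dropped silently", {
  batch <- rbind(
    med_raw("rate", 6, "mL/h", "2024-02-01T10:00:00Z", "2024-02-01T14:00:00Z"),
    med_raw("volume", 30, "mL", "2024-02-01T10:00:00Z", NA),       # no interval
    med_raw("dose", 1, "mL", "2024-02-01T10:00:00Z"),              # wrong dimension
    med_raw("rate", 1, "mL/h", "2024-02-01T10:00:00Z",
            "2024-02-01T14:00:00Z", drug_id = "NOPE")              # uncataloged
  )
  batch$record_id <- sprintf("M%d", 1:4)
  res <- standardize_medications(batch, med_catalog)
  expect_equal(nrow(res$events), 1L)
  expect_equal(nrow(res$failures), 3L)
  expect_setequal(res$failures$record_id, c("M2", "M3", "M4"))
  expect_equal(nrow(res$events) + nrow(res$failures), nrow(batch))
  expect_error(standardize_record(batch[4, ], med_catalog),
               class = "pdms_catalog_error")
  expect_error(standardize_record(batch[2, ], med_catalog),
               class = "pdms_unresolvable_record_error")
})

test_that("window aggregation sums boluses and pro-rates infusions", {
  events <- data.frame(
    case_id = "C1", ingredient = "testdrug_mass",
    kind = c("bolus", "bolus", "bolus", "infusion"),
    value = c(5, 3, 2, 2), unit = c("mg", "mg", "mg", "mg/h"),
    start_ts = c("2024-02-01T10:00:00Z", "2024-02-01T10:30:00Z",
                 "2024-02-01T13:00:00Z", "2024-02-01T10:00:00Z"),
    end_ts = c("2024-02-01T10:00:00Z", "2024-02-01T10:30:00Z",
               "2024-02-01T13:00:00Z", "2024-02-01T14:00:00Z"),
    stringsAsFactors = FALSE
  )
  # boluses at 10:00 and 10:30 fall in [09:45, 12:00); 13:00 does not;
  # the 2 mg/h infusion overlaps the window for 2 h
  agg <- aggregate_window(events[1:3, ], "2024-02-01T09:45:00Z",
                          "2024-02-01T12:00:00Z")
  expect_equal(agg$total, 8)
  agg2 <- aggregate_window(events[4, , drop = FALSE],
                           "2024-02-01T11:00:00Z", "2024-02-01T13:00:00Z")
  expect_equal(agg2$total, 4)
  expect_equal(agg2$unit, "mg")
  # no overlap -> zero contribution
  agg3 <- aggregate_window(events[4, , drop = FALSE],
                           "2024-02-02T10:00:00Z", "2024-02-02T12:00:00Z")
  expect_equal(agg3$total, 0)
  expect_error(aggregate_window(events, "2024-02-01T12:00:00Z",
                                "2024-02-01T10:00:00Z"),
               class = "pdms_value_error")
})

test_that("infusion aggregation is additive over adjacent windows", {
  fx <- make_fixture(n_cases = 8, seed = 83, mean_drug_events_per_case = 30)
  raw <- fetch_table(fx$handle, "medication_records")
  events <- standardize_medications(raw, load_drug_catalog(fx$handle))$events
  events <- events[events$kind == "infusion", ]
  set.seed(5)
  for (rep in 1:10) {
    a <- utc("2024-01-01 00:00:00") + runif(1, 0, 120) * 86400
    c_ <- a + runif(1, 1, 96) * 3600
    b <- a + runif(1) * as.numeric(c_ - a, units = "secs")
    whole <- aggregate_window(events, a, c_)
    left <- aggregate_window(events, a, b)
    right <- aggregate_window(events, b, c_)
    key <- paste(whole$ingredient, whole$unit)
    l <- left$total[match(key, paste(left$ingredient, left$unit))]
    r <- right$total[match(key, paste(right$ingredient, right$unit))]
    l[is.na(l)] <- 0; r[is.na(r)] <- 0
    expect_equal(whole$total, l + r, tolerance = 1e-9)
  }
})

test_that("standardized rates recover the generator's true rates exactly", {
  fx <- make_fixture(n_cases = 40, seed = 89, p_missing_end = 0,
                     p_reverify = 0, mean_drug_events_per_case = 40)
  raw <- fetch_table(fx$handle, "medication_records")
  raw <- raw[order(raw$record_id), ]
  res <- standardize_medications(raw, load_drug_catalog(fx$handle))
  expect_equal(nrow(res$failures), 0L)
  ev <- res$events[res$events$kind == "infusion", ]
  tr <- fx$ground_truth$true_rates
  expect_equal(nrow(ev), nrow(tr))
  expect_identical(ev$case_id, tr$case_id)
  expect_identical(ev$ingredient, tr$ingredient)
  expect_identical(format_utc(parse_utc(ev$start_ts)), tr$start)
  expect_lt(max(abs(ev$value - tr$rate) / tr$rate), 1e-9)
  expect_identical(ev$unit, tr$unit)
  # bolus amounts recover in the standard base unit
  bo <- res$events[res$events$kind == "bolus", ]
  tb <- fx$ground_truth$true_boluses
  expect_equal(nrow(bo), nrow(tb))
  expect_equal(bo$value, tb$amount, tolerance = 1e-9)
  expect_identical(bo$unit, tb$unit)
})

test_that("output units are dimensionally sound per ingredient", {
  fx <- make_fixture(n_cases = 20, seed = 97, mean_drug_events_per_case = 25)
  raw <- fetch_table(fx$handle, "medication_records")
  ev <- standardize_medications(raw, load_drug_catalog(fx$handle))$events
  expect_true(all(ev$unit %in% c("mg", "U", "mg/h", "U/h")))
  dims <- tapply(sub("/h$", "", ev$unit), ev$ingredient,
                 function(u) length(unique(u)))
  expect_true(all(dims == 1))
})
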