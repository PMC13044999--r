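test_that("generator configuration is validated", {
  expect_error(synthetic_config(n_cases = 0), class = "pdms_configuration_error")
  expect_error(synthetic_config(p_missing_end = 1.2),
               class = "pdms_configuration_error")
  expect_error(synthetic_config(mean_drug_events_per_case = 0),
               class = "pdms_configuration_error")
  expect_error(synthetic_config(date_range = c("2024-06-30", "2024-01-01")),
               class = "pdms_configuration_error")
  expect_error(generate_fixture(synthetic_config(), "/nonexistent-dir/x.sqlite"),
               class = "pdms_io_error")
  expect_error(generate_fixture(list(), tempfile()),
               class = "pdms_configuration_error")
})

test_that("identical config and seed give a byte-identical fixture", {
  cfg <- synthetic_config(n_cases = 15, seed = 5, mean_drug_events_per_case = 10)
  d1 <- tempfile(); d2 <- tempfile(); dir.create(d1); dir.create(d2)
  fx1 <- generate_fixture(cfg, file.path(d1, "a.sqlite"))
  fx2 <- generate_fixture(cfg, file.path(d2, "a.sqlite"))
  expect_identical(unname(tools::md5sum(fx1$path)),
                   unname(tools::md5sum(fx2$path)))
  expect_identical(readLines(fx1$ground_truth_path),
                   readLines(fx2$ground_truth_path))
  expect_identical(fx1$ground_truth, fx2$ground_truth)
  # a different seed gives different content
  fx3 <- generate_fixture(synthetic_config(n_cases = 15, seed = 6,
                                           mean_drug_events_per_case = 10),
                          file.path(d2, "b.sqlite"))
  expect_false(identical(unname(tools::md5sum(fx1$path)),
                         unname(tools::md5sum(fx3$path))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  generate_fixture(synthetic_config(n_cases = 3, seed = 1,
                                    mean_drug_events_per_case = 2),
                   file.path(tempdir(), "rng.sqlite"))
  expect_identical(runif(1), a)
})

test_that("a pathology-free case maps therapy records 1:1 to true episodes", {
  fx <- make_fixture(n_cases = 25, seed = 31, p_missing_end = 0,
                     p_reverify = 0, mean_drug_events_per_case = 5)
  recs <- fetch_table(fx$handle, "therapy_records")
  te <- fx$ground_truth$true_episodes
  expect_equal(nrow(recs), nrow(te))
  recs <- recs[order(recs$case_id, recs$device_type, recs$start_ts), ]
  te <- te[order(te$case_id, te$device_type, te$start), ]
  expect_identical(recs$start_ts, te$start)
  expect_identical(is.na(recs$end_ts), is.na(te$end))
  expect_identical(recs$end_ts[!is.na(recs$end_ts)], te$end[!is.na(te$end)])
})

test_that("pathology injection has the documented limit behaviour", {
  base <- therapy_rec(c("2024-02-01 10:00:00", "2024-02-03 08:00:00"),
                      c("2024-02-01 14:00:00", "2024-02-03 20:00:00"),
                      case_id = c("C1", "C2"))
  base$episode_id <- c("E1", "E2")
  cfg0 <- synthetic_config(n_cases = 1, p_missing_end = 0, p_reverify = 0)
  set.seed(1)
  out0 <- inject_pathologies(base, cfg0)
  expect_equal(nrow(out0), 2L)
  expect_identical(out0$start_ts, base$start_ts)
  expect_identical(out0$end_ts, base$end_ts)
  cfg1 <- synthetic_config(n_cases = 1, p_missing_end = 1, p_reverify = 0)
  set.seed(1)
  out1 <- inject_pathologies(base, cfg1)
  expect_true(all(is.na(out1$end_ts)))
  expect_true(all(out1$missing_end))
})

test_that("reverification records stay within and cover the true episode", {
  # one 10:00-14:00 episode, forced reverification: the union of the output
  # records equals the true episode
  base <- therapy_rec("2024-02-01 10:00:00", "2024-02-01 14:00:00")
  base$episode_id <- "E1"
  cfg <- synthetic_config(n_cases = 1, p_missing_end = 0, p_reverify = 1)
  set.seed(12)
  out <- inject_pathologies(base, cfg)
  expect_gte(nrow(out), 2L)
  expect_equal(min(out$start_ts), utc("2024-02-01 10:00:00"))
  expect_equal(max(out$end_ts), utc("2024-02-01 14:00:00"))
  expect_true(all(out$start_ts >= utc("2024-02-01 10:00:00")))
  expect_true(all(out$start_ts < utc("2024-02-01 14:00:00")))
  expect_true(all(out$end_ts == utc("2024-02-01 14:00:00")))
  expect_true(all(out$episode_id == "E1"))
})

test_that("a deterministic share of cases maps to multiple patient ids", {
  fx <- make_fixture(n_cases = 200, seed = 13, mean_drug_events_per_case = 2,
                     p_case_patient_conflict = 1 / 200)
  gt <- fx$ground_truth
  expect_length(gt$conflicted_cases, 1L)
  cases <- fetch_table(fx$handle, "cases")
  per_case <- tapply(cases$patient_id, cases$case_id,
                     function(p) length(unique(p)))
  expect_identical(sort(names(per_case)[per_case > 1]), gt$conflicted_cases)
  # every conflicted case still has its true identity mapping
  expect_true(all(gt$conflicted_cases %in% gt$identity_map$case_id))
})

test_that("admission windows of one patient never overlap", {
  fx <- make_fixture(n_cases = 120, seed = 17, mean_drug_events_per_case = 2)
  cases <- fetch_table(fx$handle, "cases")
  cases <- cases[!duplicated(cases$case_id), ]
  s <- as.numeric(parse_utc(cases$admission_ts))
  e <- as.numeric(parse_utc(cases$discharge_ts))
  complete <- !is.na(e)
  # direct pairwise check, independent of check_admission_overlaps()
  for (p in unique(cases$patient_id[complete])) {
    i <- which(cases$patient_id == p & complete)
    if (length(i) < 2) next
    for (a in i) for (b in setdiff(i, a)) {
      expect_true(max(s[a], s[b]) >= min(e[a], e[b]))
    }
  }
})

test_that("stored timestamps are UTC ISO-8601 at second resolution", {
  fx <- make_fixture(n_cases = 10, seed = 23, mean_drug_events_per_case = 3)
  iso_utc <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}Z$"
  for (tbl in c("cases", "bed_occupancy", "therapy_records")) {
    rows <- fetch_table(fx$handle, tbl)
    ts_cols <- grep("_ts$", names(rows), value = TRUE)
    for (col in ts_cols) {
      vals <- rows[[col]]
      expect_true(all(is.na(vals) | grepl(iso_utc, vals)),
                  label = paste(tbl, col))
    }
  }
  obs <- fetch_table(fx$handle, "observations")
  expect_true(all(grepl(iso_utc, obs$ts)))
})

test_that("ground truth serialized next to the fixture reads back", {
  fx <- make_fixture(n_cases = 12, seed = 29, mean_drug_events_per_case = 4)
  gt <- read_ground_truth(fx$ground_truth_path)
  expect_s3_class(gt, "pdms_ground_truth")
  expect_equal(nrow(gt$true_episodes), nrow(fx$ground_truth$true_episodes))
  expect_equal(gt$true_rates$rate, fx$ground_truth$true_rates$rate)
  expect_identical(gt$identity_map$case_id, fx$ground_truth$identity_map$case_id)
})
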