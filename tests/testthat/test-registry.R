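test_that("a well-formed registry parses with one entry per activity type", {
  entries <- entry_rows(
    list(date = "2021-01-15", type = "initial_encounter", minutes = 33,
         mbc = 0.8),
    list(date = "2021-02-03", type = "followup_encounter", minutes = 24,
         mbc = 0.6),
    list(date = "2021-02-10", type = "contact_attempt"),
    list(date = "2021-02-11", type = "bhc_consultation", minutes = 7)
  )
  paths <- write_temp_registry(entries, patient_rows())
  reg <- read_registry(paths$entries, paths$patients)
  expect_s3_class(reg, "cocm_registry")
  expect_equal(nrow(reg$entries), 4)
  expect_setequal(reg$entries$activity_type, activity_types())
  # contact attempts carry no minutes in raw input
  expect_true(is.na(reg$entries$minutes[
    reg$entries$activity_type == "contact_attempt"]))
  expect_equal(nrow(attr(reg$entries, "rejected")), 0)
  expect_false(reg$patients$is_fqhc)
})

test_that("invalid rows are rejected individually with diagnostics", {
  entries <- entry_rows(
    list(date = "2021-01-15", type = "initial_encounter", minutes = 33),
    list(date = "2021-01-16", type = "followup_encounter", minutes = -5),
    list(date = "2021-01-17", type = "contact_attempt", minutes = 5),
    list(date = "2021-01-18", type = "bhc_consultation", minutes = 7,
         mbc = 0.5),
    list(date = "2021-01-19", type = "followup_encounter", minutes = 10,
         mbc = 1.4)
  )
  paths <- write_temp_registry(entries, patient_rows())
  expect_warning(reg <- read_registry(paths$entries, paths$patients),
                 "rejected 4")
  expect_equal(nrow(reg$entries), 1)
  rej <- attr(reg$entries, "rejected")
  expect_equal(nrow(rej), 4)
  expect_true(any(grepl("nonnegative", rej$reason)))
  expect_true(any(grepl("contact attempts must not carry minutes",
                        rej$reason)))
  expect_true(any(grepl("only allowed on care-manager", rej$reason)))
  expect_true(any(grepl("outside \\[0, 1\\]", rej$reason)))
  expect_true(all(rej$row > 0))
})

test_that("a missing required column is a schema error naming the column", {
  entries <- entry_rows(list(date = "2021-01-15", type = "initial_encounter",
                             minutes = 33))
  paths <- write_temp_registry(entries, patient_rows())
  raw <- utils::read.csv(paths$entries)
  raw$minutes <- NULL
  utils::write.csv(raw, paths$entries, row.names = FALSE)
  expect_error(read_registry(paths$entries, paths$patients), "minutes")
  expect_error(read_registry("no-such-file.csv", paths$patients),
               "no-such-file")
})

test_that("contact-minute imputation fills attempts and leaves the rest", {
  entries <- entry_rows(
    list(date = "2021-01-15", type = "contact_attempt"),
    list(date = "2021-01-16", type = "contact_attempt"),
    list(date = "2021-01-17", type = "contact_attempt"),
    list(date = "2021-01-18", type = "followup_encounter", minutes = 24)
  )
  out <- impute_contact_minutes(entries, 5)
  expect_equal(sum(out$minutes[out$activity_type == "contact_attempt"]), 15)
  expect_equal(out$minutes[out$activity_type == "followup_encounter"], 24)
  expect_error(impute_contact_minutes(entries, 0), "positive")
  expect_error(impute_contact_minutes(entries, -5), "positive")
})

test_that("trial-scale attempt volumes rescale exactly linearly", {
  # 4,747 attempts at 5 minutes give 23,735 total contact minutes; the same
  # attempts at 10 minutes give 47,470 (the sensitivity assumption)
  n <- 4747
  attempts <- data.frame(activity_type = rep("contact_attempt", n),
                         minutes = NA_real_)
  expect_equal(sum(impute_contact_minutes(attempts, 5)$minutes), 23735)
  expect_equal(sum(impute_contact_minutes(attempts, 10)$minutes), 47470)
})

test_that("aggregation sums minutes and sets the service flags", {
  entries <- entry_rows(
    list(date = "2021-01-15", type = "initial_encounter", minutes = 33,
         mbc = 0.8),
    list(date = "2021-01-20", type = "bhc_consultation", minutes = 7)
  )
  months <- aggregate_months(entries, patient_rows())
  expect_equal(nrow(months), 1)
  expect_equal(months$total_minutes, 40)
  expect_true(months$has_cm_encounter)
  expect_true(months$has_bhc_consult)
  expect_true(months$has_mbc)
  expect_equal(months$month_index, 1)
})

test_that("MBC below the completeness threshold does not count", {
  entries <- entry_rows(
    list(date = "2021-01-15", type = "followup_encounter", minutes = 20,
         mbc = 0.4)
  )
  months <- aggregate_months(entries, patient_rows())
  expect_false(months$has_mbc)
  expect_true(aggregate_months(entries, patient_rows(),
                               mbc_threshold = 0.3)$has_mbc)
  # a precomputed completeness flag takes precedence over the fraction
  entries$mbc_complete <- TRUE
  expect_true(aggregate_months(entries, patient_rows())$has_mbc)
})

test_that("the intervention window is half-open at six calendar months", {
  rand <- "2021-01-10"
  entries <- entry_rows(
    list(date = "2021-01-10", type = "followup_encounter", minutes = 10,
         mbc = 0.9),
    list(date = "2021-07-09", type = "followup_encounter", minutes = 11),
    list(date = "2021-07-10", type = "followup_encounter", minutes = 12),
    list(date = "2021-08-20", type = "followup_encounter", minutes = 13)
  )
  months <- aggregate_months(entries, patient_rows(rand = rand))
  # the day before the 6-month anniversary is in; the anniversary is out
  expect_equal(sum(months$total_minutes), 21)
  expect_equal(months$year_month, c("2021-01", "2021-07"))
  # day-anchored variant
  months_d <- aggregate_months(entries, patient_rows(rand = rand),
                               window_type = "days", window_days = 183)
  expect_equal(sum(months_d$total_minutes), 33)
})

test_that("entries before randomization are rejected with a diagnostic", {
  entries <- entry_rows(
    list(date = "2021-01-05", type = "contact_attempt"),
    list(date = "2021-01-15", type = "followup_encounter", minutes = 10)
  )
  entries <- impute_contact_minutes(entries, 5)
  expect_warning(
    months <- aggregate_months(entries, patient_rows(rand = "2021-01-10")),
    "before randomization"
  )
  expect_equal(sum(months$total_minutes), 10)
  expect_equal(nrow(attr(months, "rejected")), 1)
  expect_error(
    aggregate_months(
      impute_contact_minutes(
        entry_rows(list(patient = "ghost", date = "2021-01-15",
                        type = "contact_attempt")), 5),
      patient_rows()),
    "unknown patient_id")
})

test_that("aggregation conserves in-window minutes and scales attempts linearly", {
  for (seed in 1:3) {
    reg <- simulate_registry(sim_params(n_patients = 30, seed = seed))
    e5 <- impute_contact_minutes(reg$entries, 5)
    months <- aggregate_months(e5, reg$patients)
    # independent in-window accounting straight off the entry table
    rand <- reg$patients$randomization_date[
      match(e5$patient_id, reg$patients$patient_id)]
    in_window <- e5$date >= rand & e5$date < add_months(rand, 6)
    expect_equal(sum(months$total_minutes), sum(e5$minutes[in_window]))
    expect_equal(sum(months$total_minutes),
                 sum(months$minutes_initial) + sum(months$minutes_followup) +
                   sum(months$minutes_attempt) + sum(months$minutes_bhc))
    # switching the per-attempt assumption rescales only attempt minutes
    e10 <- impute_contact_minutes(reg$entries, 10)
    months10 <- aggregate_months(e10, reg$patients)
    expect_equal(sum(months10$minutes_attempt),
                 2 * sum(months$minutes_attempt))
    expect_equal(sum(months10$minutes_followup),
                 sum(months$minutes_followup))
    expect_equal(sum(months10$total_minutes) - sum(months$total_minutes),
                 sum(months$minutes_attempt))
  }
})
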