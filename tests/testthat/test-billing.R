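expansive <- scenario_config("expansive")
restrictive <- scenario_config("restrictive")

items_of <- function(dec, month = 1) {
  it <- dec$items[dec$items$year_month == sprintf("2021-%02d", month), ]
  stats::setNames(it$credited_minutes, it$code)
}

test_that("half-plus-one minimums match the published ranges", {
  expect_equal(half_plus_one_minimum(70), 36L)
  expect_equal(half_plus_one_minimum(60), 31L)
  expect_equal(half_plus_one_minimum(30), 16L)
  expect_error(half_plus_one_minimum(0), "positive")
  codes <- billing_codes()
  rng <- codes[codes$time_model == "range", ]
  expect_equal(rng$min_minutes, half_plus_one_minimum(rng$max_minutes))
  expect_equal(codes$frequency_limit[codes$code == "99494"], 2L)
  expect_true(all(codes$frequency_limit[codes$code != "99494"] == 1L))
})

test_that("non-FQHC CoCM months bill the base code then add-ons", {
  # initial month fitting the 99492 range
  dec <- bill_months(50, scenario = expansive)
  expect_equal(items_of(dec), c("99492" = 50))
  expect_equal(dec$decisions$billable_minutes, 50)
  expect_equal(dec$decisions$unb_over_maximum, 0)

  # long follow-up month: base at max, two add-ons, remainder over-maximum
  dec <- bill_months(c(50, 140), scenario = expansive)
  expect_equal(items_of(dec, 2), c("99493" = 60, "99494" = 30, "99494" = 30))
  expect_equal(dec$decisions$billable_minutes[2], 120)
  expect_equal(dec$decisions$unb_over_maximum[2], 20)

  # one add-on only when the residual supports it
  dec <- bill_months(c(50, 80), scenario = expansive)
  expect_equal(items_of(dec, 2), c("99493" = 60, "99494" = 20))
  dec <- bill_months(c(50, 75), scenario = expansive)
  expect_equal(items_of(dec, 2), c("99493" = 60))
  expect_equal(dec$decisions$unb_over_maximum[2], 15)
})

test_that("under-minimum CoCM months fall back to the management code", {
  # follow-up month below 31 minutes: G2214 in the expansive scenario
  dec <- bill_months(c(50, 25), scenario = expansive)
  expect_equal(items_of(dec, 2), c("G2214" = 25))
  # the same month with G2214 excluded is scenario-unavailable
  dec <- bill_months(c(50, 25), scenario = restrictive)
  expect_equal(nrow(dec$items[dec$items$year_month == "2021-02", ]), 0)
  expect_equal(dec$decisions$unb_restricted[2], 25)
  # the initial-month 31-35 gap credits 30 with the excess over-maximum
  dec <- bill_months(33, scenario = expansive)
  expect_equal(items_of(dec), c("G2214" = 30))
  expect_equal(dec$decisions$unb_over_maximum, 3)
  # below every threshold
  dec <- bill_months(10, scenario = expansive)
  expect_equal(nrow(dec$items), 0)
  expect_equal(dec$decisions$unb_under_minimum, 10)
})

test_that("the initial CoCM code is deferred past under-minimum months", {
  # month 1 under the 99492 minimum bills G2214; 99492 still available in
  # month 2
  dec <- bill_months(c(20, 50), scenario = expansive)
  expect_equal(items_of(dec, 1), c("G2214" = 20))
  expect_equal(items_of(dec, 2), c("99492" = 50))
  # canonical initial-then-follow-up
  dec <- bill_months(c(50, 40), scenario = expansive)
  expect_equal(items_of(dec, 1), c("99492" = 50))
  expect_equal(items_of(dec, 2), c("99493" = 40))
  # once 99492 is billed it never recurs
  dec <- bill_months(c(50, 40, 45), scenario = expansive)
  expect_equal(unname(table(dec$items$code)["99492"]), 1L)
  expect_equal(unname(table(dec$items$code)["99493"]), 2L)
  # a BHI-only month does not start the follow-up sequence either
  dec <- bill_months(c(40, 50), bhc = c(FALSE, TRUE), scenario = expansive)
  expect_equal(items_of(dec, 1), c("99484" = 20))
  expect_equal(items_of(dec, 2), c("99492" = 50))
})

test_that("FQHC months bill G0512 at the set amount or fall back to G0511", {
  # first qualifying month needs 70 minutes and credits exactly 70
  dec <- bill_months(80, fqhc = TRUE, scenario = expansive)
  expect_equal(items_of(dec), c("G0512" = 70))
  expect_equal(dec$decisions$unb_over_maximum, 10)
  # under the G0512 minimum: G0511 credits exactly 20
  dec <- bill_months(45, fqhc = TRUE, scenario = expansive)
  expect_equal(items_of(dec), c("G0511" = 20))
  expect_equal(dec$decisions$unb_over_maximum, 25)
  # the 70-minute first-instance threshold attaches to the first G0512
  dec <- bill_months(c(40, 75), fqhc = TRUE, scenario = expansive)
  expect_equal(items_of(dec, 1), c("G0511" = 20))
  expect_equal(dec$decisions$unb_over_maximum[1], 20)
  expect_equal(items_of(dec, 2), c("G0512" = 70))
  expect_equal(dec$decisions$unb_over_maximum[2], 5)
  # subsequent instances need only 60
  dec <- bill_months(c(70, 65), fqhc = TRUE, scenario = expansive)
  expect_equal(items_of(dec, 2), c("G0512" = 60))
  # actual-minutes crediting variant
  sc <- scenario_config("expansive", g0512_crediting = "actual_minutes")
  dec <- bill_months(80, fqhc = TRUE, scenario = sc)
  expect_equal(items_of(dec), c("G0512" = 80))
  expect_equal(dec$decisions$unb_over_maximum, 0)
})

test_that("BHI-only months bill the set-amount general BHI code", {
  dec <- bill_months(50, bhc = FALSE, scenario = expansive)
  expect_equal(items_of(dec), c("99484" = 20))
  expect_equal(dec$decisions$unb_over_maximum, 30)
  # excluded in the restrictive non-FQHC scenario
  dec <- bill_months(50, bhc = FALSE, scenario = restrictive)
  expect_equal(dec$decisions$unb_restricted, 20)
  expect_equal(dec$decisions$unb_over_maximum, 30)
  # FQHC general BHI is available in both scenarios
  for (sc in list(expansive, restrictive)) {
    dec <- bill_months(50, bhc = FALSE, fqhc = TRUE, scenario = sc)
    expect_equal(items_of(dec), c("G0511" = 20))
  }
  # months with no components at all are service-ineligible
  dec <- bill_months(15, cm = FALSE, bhc = FALSE, mbc = FALSE,
                     scenario = expansive)
  expect_equal(dec$decisions$unb_missing_services, 15)
})

test_that("credited minutes respect every code's printed time model", {
  set.seed(404)
  codes <- billing_codes()
  for (rep in 1:300) {
    fqhc <- runif(1) < 0.5
    cm <- runif(1) < 0.8
    mbc <- cm & runif(1) < 0.8
    bhc <- runif(1) < 0.7
    sc <- if (runif(1) < 0.5) expansive else restrictive
    totals <- sample(0:200, sample(1:4, 1), replace = TRUE)
    dec <- bill_months(totals, cm = cm, bhc = bhc, mbc = mbc, fqhc = fqhc,
                       scenario = sc)
    d <- dec$decisions
    # minute conservation in every month
    expect_equal(d$billable_minutes + d$unb_missing_services +
                   d$unb_under_minimum + d$unb_over_maximum +
                   d$unb_restricted + d$unb_not_billed,
                 d$total_minutes)
    it <- dec$items
    for (j in seq_len(nrow(it))) {
      row <- codes[codes$code == it$code[j], ]
      if (row$time_model == "range") {
        expect_gte(it$credited_minutes[j], row$min_minutes)
        expect_lte(it$credited_minutes[j], row$max_minutes)
      } else if (it$code[j] != "G0512") {
        expect_equal(it$credited_minutes[j], row$amount)
      } else {
        expect_true(it$credited_minutes[j] %in% c(60, 70))
      }
    }
    # frequency limits and exclusivity per month
    if (nrow(it)) {
      per_month <- split(it$code, it$year_month)
      for (mcodes in per_month) {
        expect_lte(sum(mcodes %in% c("99492", "99493")), 1)
        expect_lte(sum(mcodes == "99494"), 2)
        if ("99494" %in% mcodes) {
          expect_true(any(mcodes %in% c("99492", "99493")))
        }
        expect_lte(sum(mcodes == "G2214"), 1)
        expect_false(all(c("G0511", "G0512") %in% mcodes))
      }
    }
  }
})
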