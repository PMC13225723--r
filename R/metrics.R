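# Pricing and summary surfaces: fee schedules, cent-precision revenue,
# percent-billable and revenue-per-hour summaries, and the ineligibility
# taxonomies (reason partition, service-gap subsets, pre-engagement shares,
# over/under ratio).

#' Rounding and display helpers
#'
#' Printed figures use half-up rounding: currency to cents, percentages to
#' the nearest integer, ratios to one decimal.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `round_half_up()` returns a numeric vector; the `format_*`
#'   helpers return character vectors.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @export
format_currency <- function(x) {
  sprintf("%.2f", round_half_up(x, 2))
}

#' @rdname round_half_up
#' @param fraction Proportion in `[0, 1]`.
#' @export
format_percent <- function(fraction) {
  sprintf("%d%%", as.integer(round_half_up(100 * fraction, 0)))
}

#' @rdname round_half_up
#' @export
format_ratio <- function(x) {
  sprintf("%.1f", round_half_up(x, 1))
}

#' Reimbursement per hour of care management
#'
#' Total potential reimbursement divided by total documented hours — the
#' denominator is all documented minutes in scope (billable and unbillable),
#' converted to hours.
#'
#' @param revenue Total revenue in dollars.
#' @param total_minutes All documented minutes in scope.
#' @return Dollars per hour (unrounded; `NaN` when `total_minutes` is 0).
#' @examples
#' per_hour_rate(138943.19, 90996) # 91.61...
#' @export
per_hour_rate <- function(revenue, total_minutes) {
  revenue / (total_minutes / 60)
}

#' Fee schedules
#'
#' A fee schedule maps each billing code to a payment per billing instance.
#' `"medicare_2024"` ships the 2024 Medicare non-facility amounts (FQHC
#' G-code rates calculated from the relevant non-FQHC rates per CMS
#' guidance). The named Medicaid variants (`"medicaid_min"`,
#' `"medicaid_max"`) are placeholders for state schedules and require
#' user-supplied rates via `rates`.
#'
#' @param name Schedule name, a path to a JSON file of code-to-dollar rates,
#'   or a named numeric vector of rates.
#' @param rates Optional named numeric vector of dollar rates overriding or
#'   completing the named schedule.
#' @return Object of class `fee_schedule`: list with `name` and
#'   `rates_cents` (named integer cents per instance).
#' @export
fee_schedule <- function(name = "medicare_2024", rates = NULL) {
  medicare_2024 <- c("99484" = 54.92, "99492" = 153.12, "99493" = 139.81,
                     "99494" = 59.25, "G2214" = 57.25, "G0511" = 83.88,
                     "G0512" = 146.57)
  if (is.numeric(name)) {
    rates_d <- name
    name <- "custom"
  } else if (name == "medicare_2024") {
    rates_d <- medicare_2024
  } else if (name %in% c("medicaid_min", "medicaid_max")) {
    if (is.null(rates)) {
      stop(sprintf(paste0(
        "fee schedule '%s' is a placeholder: supply state Medicaid rates ",
        "via `rates` (a named vector over the active billing codes)"),
        name), call. = FALSE)
    }
    rates_d <- numeric(0)
  } else if (file.exists(name)) {
    parsed <- jsonlite::read_json(name, simplifyVector = TRUE)
    rates_d <- unlist(parsed)
    name <- sub("\\.[^.]*$", "", basename(name))
  } else {
    stop("unknown fee schedule: ", name, call. = FALSE)
  }
  if (!is.null(rates)) {
    if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
      stop("`rates` must be a named numeric vector", call. = FALSE)
    }
    rates_d[names(rates)] <- rates
  }
  if (any(rates_d < 0)) stop("fee-schedule rates must be >= 0", call. = FALSE)
  structure(
    list(name = name,
         rates_cents = round(rates_d * 100)),
    class = "fee_schedule"
  )
}

#' @export
print.fee_schedule <- function(x, ...) {
  cat(sprintf("Fee schedule '%s':\n", x$name))
  for (code in names(x$rates_cents)) {
    cat(sprintf("  %-6s $%s\n", code,
                format_currency(x$rates_cents[[code]] / 100)))
  }
  invisible(x)
}

#' Price billing decisions against a fee schedule
#'
#' Reimbursement is per billing instance: a month's revenue is the sum of
#' the schedule rate over its line items. Arithmetic is in integer cents.
#'
#' @param decisions A `cocm_decisions` object from [process_billing()].
#' @param schedule A [fee_schedule()].
#' @return `decisions` with `revenue_cents` added to both the per-month
#'   `decisions` table and the `items` table, and the schedule attached.
#' @export
price_decisions <- function(decisions, schedule = fee_schedule()) {
  stopifnot(inherits(decisions, "cocm_decisions"),
            inherits(schedule, "fee_schedule"))
  items <- decisions$items
  unknown <- setdiff(unique(items$code), names(schedule$rates_cents))
  if (length(unknown)) {
    stop("fee schedule '", schedule$name, "' has no rate for billed code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  items$revenue_cents <- if (nrow(items)) {
    as.numeric(schedule$rates_cents[items$code])
  } else {
    numeric(0)
  }
  d <- decisions$decisions
  key <- paste(d$patient_id, d$year_month, sep = "\r")
  ikey <- paste(items$patient_id, items$year_month, sep = "\r")
  rev <- tapply(items$revenue_cents, ikey, sum)
  d$revenue_cents <- as.numeric(rev[match(key, names(rev))])
  d$revenue_cents[is.na(d$revenue_cents)] <- 0
  decisions$decisions <- d
  decisions$items <- items
  decisions$schedule <- schedule
  decisions
}

#' Summarize priced decisions
#'
#' Produces the headline summary for a scope: total documented minutes and
#' hours, billable minutes, percent billable, total potential reimbursement,
#' reimbursement per hour of care management (revenue divided by all
#' documented hours in scope), minutes and instances by code, the
#' unbillable-minute partition by reason, and pre-engagement tallies.
#'
#' @param priced A priced `cocm_decisions` (see [price_decisions()]).
#' @param scope `"combined"`, `"fqhc"` or `"non_fqhc"`.
#' @return Object of class `cocm_report`.
#' @export
summarize_billing <- function(priced,
                              scope = c("combined", "fqhc", "non_fqhc")) {
  scope <- match.arg(scope)
  stopifnot(inherits(priced, "cocm_decisions"))
  if (is.null(priced$decisions$revenue_cents)) {
    stop("decisions are unpriced; run price_decisions() first", call. = FALSE)
  }
  d <- priced$decisions
  keep <- switch(scope, combined = rep(TRUE, nrow(d)), fqhc = d$is_fqhc,
                 non_fqhc = !d$is_fqhc)
  d <- d[keep, , drop = FALSE]
  ikey <- paste(priced$items$patient_id, priced$items$year_month, sep = "\r")
  dkey <- paste(d$patient_id, d$year_month, sep = "\r")
  items <- priced$items[ikey %in% dkey, , drop = FALSE]

  total_minutes <- sum(d$total_minutes)
  billable_minutes <- sum(d$billable_minutes)
  revenue_cents <- sum(d$revenue_cents)
  unbillable <- c(
    missing_services = sum(d$unb_missing_services),
    under_minimum = sum(d$unb_under_minimum),
    over_maximum = sum(d$unb_over_maximum),
    restricted = sum(d$unb_restricted),
    not_billed = sum(d$unb_not_billed)
  )
  minutes_by_code <- if (nrow(items)) {
    tapply(items$credited_minutes, items$code, sum)
  } else {
    numeric(0)
  }
  instances_by_code <- if (nrow(items)) {
    tapply(rep(1L, nrow(items)), items$code, sum)
  } else {
    integer(0)
  }
  pre_unb <- sum((d$total_minutes - d$billable_minutes)[d$pre_engagement])
  gap_minutes <- if (any(!d$cocm_met)) {
    tapply(d$total_minutes[!d$cocm_met], d$gap_category[!d$cocm_met], sum)
  } else {
    numeric(0)
  }

  structure(list(
    scope = scope,
    scenario = priced$scenario$name,
    fee_schedule = priced$schedule$name,
    n_patients = length(unique(d$patient_id)),
    n_months = nrow(d),
    empty = nrow(d) == 0,
    total_minutes = total_minutes,
    total_hours = total_minutes / 60,
    billable_minutes = billable_minutes,
    percent_billable = if (total_minutes > 0) {
      billable_minutes / total_minutes
    } else {
      0
    },
    total_revenue = revenue_cents / 100,
    revenue_per_hour = if (total_minutes > 0) {
      per_hour_rate(revenue_cents / 100, total_minutes)
    } else {
      0
    },
    minutes_by_code = c(minutes_by_code),
    instances_by_code = c(instances_by_code),
    unbillable_by_reason = unbillable,
    service_gap_minutes = c(gap_minutes),
    pre_engagement_unbillable_minutes = pre_unb,
    pre_engagement_share_of_unbillable = if (sum(unbillable) > 0) {
      pre_unb / sum(unbillable)
    } else {
      NA_real_
    },
    pre_engagement_share_of_total = if (total_minutes > 0) {
      pre_unb / total_minutes
    } else {
      NA_real_
    }
  ), class = "cocm_report")
}

#' Tally reasons for billing ineligibility
#'
#' Minutes by ineligibility reason (service requirements missing — with the
#' service-gap subset detail —, under the minimum billable time, over the
#' maximum, or only billable under codes excluded from the scenario), the
#' ratio of over-maximum to under-minimum minutes, and pre-engagement
#' unbillable minutes with their shares of all unbillable and of all
#' documented minutes.
#'
#' @param priced A priced `cocm_decisions`.
#' @param scope As in [summarize_billing()].
#' @return List with `unbillable_by_reason`, `service_gap_minutes`,
#'   `over_under_ratio` (`NA` unless both over-maximum and under-minimum
#'   minutes occur),
#'   `pre_engagement_unbillable_minutes` and the two share fields.
#' @export
ineligibility_breakdown <- function(priced, scope = "combined") {
  rep <- summarize_billing(priced, scope)
  under <- rep$unbillable_by_reason[["under_minimum"]]
  over <- rep$unbillable_by_reason[["over_maximum"]]
  list(
    unbillable_by_reason = rep$unbillable_by_reason,
    service_gap_minutes = rep$service_gap_minutes,
    over_under_ratio = if (under > 0 && over > 0) over / under else NA_real_,
    pre_engagement_unbillable_minutes =
      rep$pre_engagement_unbillable_minutes,
    pre_engagement_share_of_unbillable =
      rep$pre_engagement_share_of_unbillable,
    pre_engagement_share_of_total = rep$pre_engagement_share_of_total
  )
}

#' @export
print.cocm_report <- function(x, ...) {
  cat(sprintf("CoCM reimbursement summary [%s, scenario: %s, fees: %s]\n",
              x$scope, x$scenario, x$fee_schedule))
  cat(sprintf("  Patients / patient-months:        %d / %d\n",
              x$n_patients, x$n_months))
  cat(sprintf("  Total minutes:                    %s\n",
              format(x$total_minutes, big.mark = ",")))
  cat(sprintf("  Total hours:                      %s\n",
              format(round(x$total_hours), big.mark = ",")))
  cat(sprintf("  Minutes eligible to bill:         %s\n",
              format(x$billable_minutes, big.mark = ",")))
  cat(sprintf("  Percent of minutes eligible:      %s\n",
              format_percent(x$percent_billable)))
  cat(sprintf("  Potential reimbursement:          $%s\n",
              format_currency(x$total_revenue)))
  cat(sprintf("  Reimbursement per hour of CoCM:   $%s\n",
              format_currency(x$revenue_per_hour)))
  if (length(x$minutes_by_code)) {
    cat("  Billable minutes by code:\n")
    for (code in names(x$minutes_by_code)) {
      cat(sprintf("    %-6s %s min (%d instance%s)\n", code,
                  format(x$minutes_by_code[[code]], big.mark = ","),
                  x$instances_by_code[[code]],
                  if (x$instances_by_code[[code]] == 1) "" else "s"))
    }
  }
  cat("  Unbillable minutes by reason:\n")
  for (r in names(x$unbillable_by_reason)) {
    cat(sprintf("    %-18s %s\n", r,
                format(x$unbillable_by_reason[[r]], big.mark = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.cocm_report <- function(x, ...) {
  data.frame(
    variable = c("scope", "scenario", "fee_schedule", "total_minutes",
                 "total_hours", "minutes_eligible_to_bill",
                 "percent_eligible", "potential_reimbursement",
                 "reimbursement_per_hour"),
    value = c(x$scope, x$scenario, x$fee_schedule,
              as.character(x$total_minutes),
              as.character(round(x$total_hours)),
              as.character(x$billable_minutes),
              as.character(as.integer(round_half_up(
                100 * x$percent_billable))),
              format_currency(x$total_revenue),
              format_currency(x$revenue_per_hour)),
    stringsAsFactors = FALSE
  )
}
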