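# Scenario configuration and orchestration: the expansive/restrictive code
# presets, the full pipeline from raw entries to summary reports, the
# scenario grid, and the three sensitivity knobs (Medicaid-style fee
# schedules, 10-minute contact attempts, unbilled-month fraction).

#' Configure an analysis scenario
#'
#' Bundles every tunable of a pipeline run: the care setting, which billing
#' codes are available (the `"expansive"` preset assumes all seven codes are
#' reimbursable; `"restrictive"` keeps only the commonly reimbursed subset,
#' dropping 99484 and G2214 for non-FQHCs and nothing for FQHCs), the fee
#' schedule, the assumed minutes per contact attempt (5 by default, 10 as
#' the plausible maximum), the fraction of billable months assumed to go
#' unbilled in practice, and the intervention-window and MBC-completeness
#' parameters.
#'
#' @param name Scenario label used in outputs.
#' @param setting `"both"`, `"fqhc"` or `"non_fqhc"`.
#' @param codes `"expansive"`, `"restrictive"`, or a named logical vector
#'   over the seven codes (missing names default to the expansive preset).
#' @param fees A [fee_schedule()].
#' @param contact_attempt_minutes Assumed minutes per contact attempt.
#' @param unbilled_fraction Fraction in `[0, 1)` of billable months assumed
#'   not billed (see [apply_unbilled_fraction()]).
#' @param unbilled_mode `"deterministic_scaling"` or `"random_month_drop"`.
#' @param seed Integer seed; required when `unbilled_mode` is
#'   `"random_month_drop"`.
#' @param g0512_crediting `"set_amount"` (credit exactly 70/60 minutes,
#'   default) or `"actual_minutes"` for qualifying G0512 months.
#' @param window_months,window_type,window_days,mbc_threshold Passed to
#'   [aggregate_months()].
#' @return Object of class `cocm_scenario`.
#' @export
scenario_config <- function(name = "expansive",
                            setting = c("both", "fqhc", "non_fqhc"),
                            codes = name,
                            fees = fee_schedule("medicare_2024"),
                            contact_attempt_minutes = 5,
                            unbilled_fraction = 0,
                            unbilled_mode = c("deterministic_scaling",
                                              "random_month_drop"),
                            seed = NULL,
                            g0512_crediting = c("set_amount",
                                                "actual_minutes"),
                            window_months = 6,
                            window_type = "calendar",
                            window_days = 183,
                            mbc_threshold = 0.5) {
  setting <- match.arg(setting)
  unbilled_mode <- match.arg(unbilled_mode)
  g0512_crediting <- match.arg(g0512_crediting)
  all_codes <- billing_codes()$code

  if (is.character(codes) && length(codes) == 1) {
    avail <- switch(codes,
      expansive = stats::setNames(rep(TRUE, length(all_codes)), all_codes),
      restrictive = stats::setNames(billing_codes()$in_restrictive,
                                    all_codes),
      stop("unknown code preset: ", codes,
           " (use 'expansive', 'restrictive', or a named logical vector)",
           call. = FALSE)
    )
  } else {
    if (!is.logical(codes) || is.null(names(codes))) {
      stop("`codes` must be a preset name or a named logical vector",
           call. = FALSE)
    }
    bad <- setdiff(names(codes), all_codes)
    if (length(bad)) {
      stop("unknown billing code(s) in availability map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    avail <- stats::setNames(rep(TRUE, length(all_codes)), all_codes)
    avail[names(codes)] <- codes
  }

  if (!inherits(fees, "fee_schedule")) fees <- fee_schedule(fees)
  if (!is.numeric(contact_attempt_minutes) || contact_attempt_minutes <= 0) {
    stop("contact_attempt_minutes must be positive", call. = FALSE)
  }
  if (!is.numeric(unbilled_fraction) || unbilled_fraction < 0 ||
      unbilled_fraction >= 1) {
    stop("unbilled_fraction must be in [0, 1)", call. = FALSE)
  }
  if (unbilled_mode == "random_month_drop" && unbilled_fraction > 0 &&
      is.null(seed)) {
    stop("random_month_drop requires a seed", call. = FALSE)
  }

  structure(list(
    name = name, setting = setting, codes = avail, fees = fees,
    contact_attempt_minutes = contact_attempt_minutes,
    unbilled_fraction = unbilled_fraction, unbilled_mode = unbilled_mode,
    seed = seed, g0512_crediting = g0512_crediting,
    window_months = window_months, window_type = window_type,
    window_days = window_days, mbc_threshold = mbc_threshold
  ), class = "cocm_scenario")
}

#' @export
print.cocm_scenario <- function(x, ...) {
  cat(sprintf("CoCM scenario '%s' (%s setting)\n", x$name, x$setting))
  cat("  codes available: ",
      paste(names(x$codes)[x$codes], collapse = ", "), "\n", sep = "")
  cat(sprintf("  fee schedule: %s; contact attempt: %g min\n",
              x$fees$name, x$contact_attempt_minutes))
  if (x$unbilled_fraction > 0) {
    cat(sprintf("  unbilled fraction: %g (%s)\n", x$unbilled_fraction,
                x$unbilled_mode))
  }
  invisible(x)
}

# Evaluate seeded code with the RNG state restored afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Discount revenue for months assumed to go unbilled
#'
#' Practices actively using the CoCM codes may fail to bill a share of the
#' months that were eligible. Two readings are provided:
#' `"deterministic_scaling"` multiplies every month's revenue by
#' `1 - fraction` (minute tallies unchanged); `"random_month_drop"` zeroes
#' the revenue and billable-minute credit of a seeded Bernoulli(`fraction`)
#' subset of billable months, so the expected discount equals the
#' deterministic one.
#'
#' @param priced A priced `cocm_decisions`.
#' @param fraction Fraction in `[0, 1)` of eligible months not billed.
#' @param mode `"deterministic_scaling"` or `"random_month_drop"`.
#' @param seed Integer seed (required for `"random_month_drop"`).
#' @return The adjusted `cocm_decisions`.
#' @export
apply_unbilled_fraction <- function(priced, fraction,
                                    mode = c("deterministic_scaling",
                                             "random_month_drop"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(priced, "cocm_decisions"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  if (fraction == 0) return(priced)
  d <- priced$decisions
  if (is.null(d$revenue_cents)) {
    stop("decisions are unpriced; run price_decisions() first", call. = FALSE)
  }
  if (mode == "deterministic_scaling") {
    d$revenue_cents <- d$revenue_cents * (1 - fraction)
  } else {
    if (is.null(seed)) {
      stop("random_month_drop requires a seed", call. = FALSE)
    }
    billable <- d$billable_minutes > 0
    drop <- logical(nrow(d))
    drop[billable] <- .with_seed(seed,
                                 stats::runif(sum(billable)) < fraction)
    d$revenue_cents[drop] <- 0
    d$unb_not_billed[drop] <- d$unb_not_billed[drop] +
      d$billable_minutes[drop]
    d$billable_minutes[drop] <- 0
    ikey <- paste(priced$items$patient_id, priced$items$year_month,
                  sep = "\r")
    dkey <- paste(d$patient_id, d$year_month, sep = "\r")[drop]
    priced$items <- priced$items[!(ikey %in% dkey), , drop = FALSE]
  }
  priced$decisions <- d
  priced
}

#' Run the full pipeline under one scenario
#'
#' Imputes contact-attempt minutes, aggregates patient-months over the
#' intervention window, evaluates service requirements and engagement,
#' assigns billing codes, prices them, applies any unbilled-fraction
#' adjustment, and summarizes by scope.
#'
#' @param entries Registry entry data frame (raw; contact-attempt minutes
#'   may be absent).
#' @param patients Patient data frame.
#' @param scenario A `cocm_scenario` from [scenario_config()].
#' @return Object of class `cocm_run`: `reports` (named list of
#'   `cocm_report` for `combined`, `non_fqhc` and `fqhc` as applicable),
#'   plus the intermediate `months`, `profiles`, `decisions` and the
#'   resolved `scenario`.
#' @export
run_scenario <- function(entries, patients, scenario = scenario_config()) {
  stopifnot(inherits(scenario, "cocm_scenario"))
  if (inherits(entries, "cocm_registry")) {
    patients <- entries$patients
    entries <- entries$entries
  }
  if (scenario$setting != "both") {
    keep <- if (scenario$setting == "fqhc") patients$is_fqhc else
      !patients$is_fqhc
    patients <- patients[keep, , drop = FALSE]
    entries <- entries[entries$patient_id %in% patients$patient_id, ,
                       drop = FALSE]
  }
  entries <- impute_contact_minutes(entries,
                                    scenario$contact_attempt_minutes)
  months <- aggregate_months(entries, patients,
                             window_months = scenario$window_months,
                             mbc_threshold = scenario$mbc_threshold,
                             window_type = scenario$window_type,
                             window_days = scenario$window_days)
  profiles <- engagement_timeline(evaluate_services(months))
  decisions <- process_billing(profiles, scenario)
  priced <- price_decisions(decisions, scenario$fees)
  priced <- apply_unbilled_fraction(priced, scenario$unbilled_fraction,
                                    scenario$unbilled_mode, scenario$seed)
  scopes <- switch(scenario$setting,
                   both = c("combined", "non_fqhc", "fqhc"),
                   fqhc = "fqhc",
                   non_fqhc = "non_fqhc")
  reports <- lapply(scopes, function(s) summarize_billing(priced, s))
  names(reports) <- scopes
  structure(list(reports = reports, months = months, profiles = profiles,
                 decisions = priced, scenario = scenario),
            class = "cocm_run")
}

#' @export
print.cocm_run <- function(x, ...) {
  for (r in x$reports) {
    print(r)
    cat("\n")
  }
  invisible(x)
}

#' Run the expansive/restrictive scenario grid
#'
#' Runs the pipeline under both code-availability presets and summarizes
#' each by combined, non-FQHC and FQHC scope: six internally consistent
#' reports.
#'
#' @param entries,patients As in [run_scenario()].
#' @param base Scenario whose non-preset parameters (fees, contact-attempt
#'   minutes, window, ...) are shared by both runs.
#' @return Object of class `cocm_grid`: list of `cocm_run` keyed
#'   `expansive` and `restrictive`.
#' @export
scenario_grid <- function(entries, patients, base = scenario_config()) {
  runs <- lapply(c("expansive", "restrictive"), function(preset) {
    sc <- base
    sc$name <- preset
    sc$codes <- scenario_config(preset)$codes
    run_scenario(entries, patients, sc)
  })
  names(runs) <- c("expansive", "restrictive")
  structure(runs, class = "cocm_grid")
}

#' @export
print.cocm_grid <- function(x, ...) {
  for (run in x) print(run)
  invisible(x)
}
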