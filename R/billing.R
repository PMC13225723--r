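# Billing-code assignment. Implements the CPT/HCPCS time rules for the CoCM
# and general-BHI code families: half-plus-one minimums for ranged codes,
# set-amount crediting for the flat codes, code precedence and fallbacks,
# deferral of the initial-month CoCM code, the two-instance add-on limit, and
# categorization of unbillable minutes.

#' Half-plus-one minimum billing time
#'
#' CPT timed codes may be billed once service time reaches 50% of the
#' maximum billable time plus one minute, i.e. `floor(max/2) + 1`.
#'
#' @param max_minutes Maximum billable minutes for the code (positive).
#' @return The minimum billable minutes.
#' @examples
#' half_plus_one_minimum(70) # 36
#' half_plus_one_minimum(60) # 31
#' half_plus_one_minimum(30) # 16
#' @export
half_plus_one_minimum <- function(max_minutes) {
  if (!is.numeric(max_minutes) || any(is.na(max_minutes)) ||
      any(max_minutes < 1)) {
    stop("max_minutes must be a positive integer", call. = FALSE)
  }
  as.integer(floor(max_minutes / 2) + 1)
}

#' Billing codes for CoCM and general BHI
#'
#' The seven codes considered, with their time model and monthly frequency
#' limit. Ranged codes (99492, 99493, 99494, G2214) follow the half-plus-one
#' rule; set-amount codes credit a fixed quantum (20 minutes for the general
#' BHI codes 99484/G0511; 70 first month / 60 subsequent for the FQHC CoCM
#' code G0512). `in_restrictive` marks codes retained in the restrictive
#' scenario: the commonly reimbursed subset, which drops 99484 and G2214 for
#' non-FQHCs and nothing for FQHCs.
#'
#' @return Data frame with one row per code: `code`, `setting`
#'   (`"non_fqhc"`/`"fqhc"`), `time_model` (`"range"`/`"set"`), `min_minutes`,
#'   `max_minutes` (range codes), `amount` and `qualifying_min` (set codes),
#'   `frequency_limit`, `role` and `in_restrictive`.
#' @export
billing_codes <- function() {
  df <- data.frame(
    code = c("99484", "99492", "99493", "99494", "G2214", "G0511", "G0512"),
    setting = c(rep("non_fqhc", 5), "fqhc", "fqhc"),
    time_model = c("set", "range", "range", "range", "range", "set", "set"),
    min_minutes = c(NA, half_plus_one_minimum(c(70, 60, 30, 30)), NA, NA),
    max_minutes = c(NA, 70, 60, 30, 30, NA, NA),
    amount = c(20, NA, NA, NA, NA, 20, NA),
    qualifying_min = c(20, NA, NA, NA, NA, 20, NA),
    frequency_limit = c(1L, 1L, 1L, 2L, 1L, 1L, 1L),
    role = c("general_bhi", "cocm_base_initial", "cocm_base_followup",
             "cocm_addon", "cocm_management", "general_bhi", "cocm_fqhc"),
    in_restrictive = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  df
}

# G0512 is a set-amount code whose quantum depends on whether it is the
# patient's first billed instance: 70 minutes first, 60 subsequently.
.g0512_amount <- function(first) if (first) 70L else 60L

.empty_reasons <- function() {
  c(missing_services = 0, under_minimum = 0, over_maximum = 0,
    restricted = 0)
}

# Assign codes to a single month. Returns list(codes, credited, reasons,
# billed_initial, billed_g0512). `avail` is a named logical over the seven
# codes; `initial_billed`/`g0512_billed` carry the patient's cross-month
# state. `g0512_crediting` selects set-amount (default) or actual-minutes
# crediting for qualifying G0512 months.
.assign_month <- function(total, cocm_met, bhi_met, is_fqhc,
                          initial_billed, g0512_billed, avail,
                          g0512_crediting = "set_amount") {
  reasons <- .empty_reasons()
  codes <- character(0)
  credited <- numeric(0)
  billed_initial <- FALSE
  billed_g0512 <- FALSE
  bill <- function(code, minutes) {
    codes <<- c(codes, code)
    credited <<- c(credited, minutes)
  }

  if (!cocm_met && !bhi_met) {
    reasons[["missing_services"]] <- total
  } else if (!is_fqhc) {
    if (cocm_met) {
      base <- if (!initial_billed) "99492" else "99493"
      bmax <- if (base == "99492") 70 else 60
      bmin <- half_plus_one_minimum(bmax)
      if (total >= bmin) {
        # crediting under full availability: base to its max, then up to
        # two add-ons of 16-30 minutes each from the residual
        base_cred <- min(total, bmax)
        addon_creds <- numeric(0)
        residual <- total - bmax
        for (i in 1:2) {
          if (residual >= 16) {
            addon_creds <- c(addon_creds, min(residual, 30))
            residual <- residual - min(residual, 30)
          }
        }
        over <- max(residual, 0)
        if (avail[[base]]) {
          bill(base, base_cred)
          if (base == "99492") billed_initial <- TRUE
          for (cred in addon_creds) {
            if (avail[["99494"]]) {
              bill("99494", cred)
            } else {
              reasons[["restricted"]] <- reasons[["restricted"]] + cred
            }
          }
          reasons[["over_maximum"]] <- over
        } else {
          # base excluded: it "cannot be billed", so the management code
          # (then general BHI) becomes the fallback; the remainder of the
          # would-be base/add-on credit is scenario-unavailable
          would_be <- base_cred + sum(addon_creds)
          if (avail[["G2214"]]) {
            bill("G2214", min(total, 30))
          } else if (avail[["99484"]] && total >= 20) {
            bill("99484", 20)
          }
          reasons[["restricted"]] <- would_be - sum(credited)
          reasons[["over_maximum"]] <- total - would_be
        }
      } else if (total >= 16) {
        # under the base minimum: CoCM management code, else general BHI
        cred <- min(total, 30)
        if (avail[["G2214"]]) {
          bill("G2214", cred)
          reasons[["over_maximum"]] <- total - cred
        } else if (avail[["99484"]] && total >= 20) {
          bill("99484", 20)
          reasons[["over_maximum"]] <- total - 20
        } else {
          reasons[["restricted"]] <- cred
          reasons[["over_maximum"]] <- total - cred
        }
      } else {
        reasons[["under_minimum"]] <- total
      }
    } else {
      # general BHI only
      if (total >= 20) {
        if (avail[["99484"]]) {
          bill("99484", 20)
        } else {
          reasons[["restricted"]] <- 20
        }
        reasons[["over_maximum"]] <- total - 20
      } else {
        reasons[["under_minimum"]] <- total
      }
    }
  } else {
    # FQHC: G0512 for CoCM months, G0511 otherwise; both present in both
    # preset scenarios.
    if (cocm_met) {
      amount <- .g0512_amount(!g0512_billed)
      if (total >= amount) {
        if (avail[["G0512"]]) {
          cred <- if (g0512_crediting == "actual_minutes") total else amount
          bill("G0512", cred)
          billed_g0512 <- TRUE
          reasons[["over_maximum"]] <- total - cred
        } else {
          # G0512 excluded: general BHI code is the fallback
          if (avail[["G0511"]]) bill("G0511", 20)
          reasons[["restricted"]] <- amount - sum(credited)
          reasons[["over_maximum"]] <- total - amount
        }
      } else if (total >= 20) {
        if (avail[["G0511"]]) {
          bill("G0511", 20)
        } else {
          reasons[["restricted"]] <- 20
        }
        reasons[["over_maximum"]] <- total - 20
      } else {
        reasons[["under_minimum"]] <- total
      }
    } else {
      if (total >= 20) {
        if (avail[["G0511"]]) {
          bill("G0511", 20)
        } else {
          reasons[["restricted"]] <- 20
        }
        reasons[["over_maximum"]] <- total - 20
      } else {
        reasons[["under_minimum"]] <- total
      }
    }
  }

  list(codes = codes, credited = credited, reasons = reasons,
       billed_initial = billed_initial, billed_g0512 = billed_g0512)
}

#' Assign billing codes to patient-months
#'
#' Walks each patient's months in chronological order, threading the
#' cross-month billing state (whether the initial CoCM code 99492 — or, in
#' FQHCs, the first G0512 — has already been billed), and assigns codes
#' under the scenario's code availability and the time rules:
#'
#' * CoCM-eligible non-FQHC months bill 99492 (36–70 min) until the initial
#'   code has been billed, then 99493 (31–60); residual time of 16+ minutes
#'   adds up to two 99494 add-ons (16–30 each); any further excess is
#'   over-maximum.
#' * CoCM-eligible months under the base minimum fall back to G2214 (16–30),
#'   then to the general BHI code; months under every minimum are
#'   under-minimum. Billing a fallback code does not consume the initial
#'   code, which is deferred to the following month.
#' * FQHC CoCM months bill G0512 crediting a set 70 minutes for the
#'   patient's first instance and 60 thereafter (excess over-maximum), or
#'   G0511 (set 20) when under the G0512 minimum.
#' * BHI-only months (care-manager encounter and MBC but no BHC
#'   consultation) bill the general BHI code (99484 or G0511, set 20).
#' * Months whose would-be code is excluded by the restrictive scenario have
#'   those minutes categorized `restricted`; service-ineligible months are
#'   `missing_services`.
#'
#' @param profiles A `cocm_profiles` data frame with engagement flags (from
#'   [evaluate_services()] then [engagement_timeline()]).
#' @param scenario A `cocm_scenario` from [scenario_config()].
#' @return List of class `cocm_decisions`: `decisions` (one row per month:
#'   ids, minutes, `billable_minutes`, the unbillable-reason columns,
#'   `pre_engagement`) and `items` (one row per billed code instance:
#'   `patient_id`, `year_month`, `code`, `instance`, `credited_minutes`).
#' @export
process_billing <- function(profiles, scenario) {
  stopifnot(inherits(scenario, "cocm_scenario"))
  need <- c("patient_id", "year_month", "month_index", "total_minutes",
            "cocm_met", "bhi_met", "is_fqhc", "pre_engagement")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols)) {
    stop("profiles are missing column(s): ",
         paste(missing_cols, collapse = ", "),
         "; run evaluate_services() and engagement_timeline() first",
         call. = FALSE)
  }
  if (scenario$setting == "fqhc" && !all(profiles$is_fqhc)) {
    stop("scenario is FQHC-only but non-FQHC months supplied", call. = FALSE)
  }
  if (scenario$setting == "non_fqhc" && any(profiles$is_fqhc)) {
    stop("scenario is non-FQHC-only but FQHC months supplied", call. = FALSE)
  }

  ord <- order(profiles$patient_id, profiles$month_index)
  p <- as.data.frame(profiles)[ord, , drop = FALSE]
  n <- nrow(p)

  billable <- numeric(n)
  reason_mat <- matrix(0, n, 4,
                       dimnames = list(NULL, names(.empty_reasons())))
  item_rows <- vector("list", n)

  state_initial <- FALSE
  state_g0512 <- FALSE
  prev_patient <- NULL
  for (i in seq_len(n)) {
    if (!identical(p$patient_id[i], prev_patient)) {
      state_initial <- FALSE
      state_g0512 <- FALSE
      prev_patient <- p$patient_id[i]
    } else if (p$month_index[i] == p$month_index[i - 1]) {
      stop("duplicate month_index for patient ", p$patient_id[i],
           call. = FALSE)
    }
    res <- .assign_month(
      total = p$total_minutes[i],
      cocm_met = p$cocm_met[i],
      bhi_met = p$bhi_met[i],
      is_fqhc = p$is_fqhc[i],
      initial_billed = state_initial,
      g0512_billed = state_g0512,
      avail = scenario$codes,
      g0512_crediting = scenario$g0512_crediting
    )
    if (res$billed_initial) state_initial <- TRUE
    if (res$billed_g0512) state_g0512 <- TRUE
    billable[i] <- sum(res$credited)
    reason_mat[i, ] <- res$reasons
    if (length(res$codes)) {
      item_rows[[i]] <- data.frame(
        patient_id = p$patient_id[i],
        year_month = p$year_month[i],
        code = res$codes,
        instance = stats::ave(seq_along(res$codes), res$codes,
                              FUN = seq_along),
        credited_minutes = res$credited,
        stringsAsFactors = FALSE
      )
    }
  }

  decisions <- data.frame(
    patient_id = p$patient_id,
    year_month = p$year_month,
    month_index = p$month_index,
    is_fqhc = p$is_fqhc,
    total_minutes = p$total_minutes,
    billable_minutes = billable,
    unb_missing_services = reason_mat[, "missing_services"],
    unb_under_minimum = reason_mat[, "under_minimum"],
    unb_over_maximum = reason_mat[, "over_maximum"],
    unb_restricted = reason_mat[, "restricted"],
    unb_not_billed = 0,
    cocm_met = p$cocm_met,
    bhi_met = p$bhi_met,
    gap_category = p$gap_category,
    pre_engagement = p$pre_engagement,
    stringsAsFactors = FALSE
  )
  items <- do.call(rbind, item_rows[!vapply(item_rows, is.null, logical(1))])
  if (is.null(items)) {
    items <- data.frame(patient_id = character(0), year_month = character(0),
                        code = character(0), instance = integer(0),
                        credited_minutes = numeric(0),
                        stringsAsFactors = FALSE)
  }
  rownames(decisions) <- rownames(items) <- NULL
  structure(list(decisions = decisions, items = items, scenario = scenario),
            class = "cocm_decisions")
}

#' @export
print.cocm_decisions <- function(x, ...) {
  d <- x$decisions
  cat(sprintf("CoCM billing decisions: %d patient-months, %d line items\n",
              nrow(d), nrow(x$items)))
  cat(sprintf("  scenario: %s\n", x$scenario$name))
  cat(sprintf("  billable %s of %s minutes (%.0f%%)\n",
              format(sum(d$billable_minutes), big.mark = ","),
              format(sum(d$total_minutes), big.mark = ","),
              100 * sum(d$billable_minutes) / max(1, sum(d$total_minutes))))
  invisible(x)
}
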