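# Seeded synthetic registry generator. Emulates the statistical structure the
# billing analysis consumes: per-patient engagement timelines in which early
# months hold only contact attempts, Poisson activity counts per month, and
# truncated-normal encounter durations calibrated to trial-scale per-entry
# means/SDs (initial 33 (17), follow-up 24 (14), BHC consultation 7 (5)
# minutes; contact attempts carry no duration in raw output).

#' Parameters for the synthetic registry generator
#'
#' @param n_patients Number of patients.
#' @param fqhc_share Probability a patient's clinic is an FQHC.
#' @param months Intervention window length in calendar months.
#' @param delay_probs Distribution of the per-patient engagement delay:
#'   named probabilities over `"0" ... "<months-1>"` pre-engagement months
#'   plus `"never"` (patients who only ever receive contact attempts). Must
#'   sum to 1.
#' @param rate_followup,rate_bhc Expected follow-up encounters and BHC
#'   consultations per engaged month (Poisson).
#' @param rate_attempt Expected contact attempts per month, engaged or not
#'   (Poisson).
#' @param dur_initial,dur_followup,dur_bhc Length-2 numeric `(mean, sd)` of
#'   per-entry minutes. Durations are drawn from a normal truncated at >= 1
#'   minute and rounded to whole minutes; the parent normal is
#'   moment-matched so that the emitted minutes have the stated mean and SD.
#' @param mbc_prob Probability a care-manager encounter documents complete
#'   measurement-based care.
#' @param start_date First possible randomization date (ISO-8601 string or
#'   Date).
#' @param enroll_months Length of the enrollment period over which
#'   randomization dates are uniform.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_patients = 381,
                       fqhc_share = 0.5,
                       months = 6,
                       delay_probs = c("0" = 0.40, "1" = 0.14, "2" = 0.10,
                                       "3" = 0.08, "4" = 0.06, "5" = 0.04,
                                       never = 0.18),
                       rate_followup = 1.2,
                       rate_attempt = 2.1,
                       rate_bhc = 0.95,
                       dur_initial = c(33, 17),
                       dur_followup = c(24, 14),
                       dur_bhc = c(7, 5),
                       mbc_prob = 0.85,
                       start_date = "2021-01-01",
                       enroll_months = 18,
                       seed = 1L) {
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (fqhc_share < 0 || fqhc_share > 1) {
    stop("fqhc_share must be in [0, 1]", call. = FALSE)
  }
  want <- c(as.character(seq_len(months) - 1L), "never")
  if (!setequal(names(delay_probs), want)) {
    stop("delay_probs must be named over ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(delay_probs) - 1) > 1e-8 || any(delay_probs < 0)) {
    stop("delay_probs must be nonnegative and sum to 1", call. = FALSE)
  }
  for (r in c(rate_followup, rate_attempt, rate_bhc)) {
    if (!is.numeric(r) || r < 0) stop("rates must be >= 0", call. = FALSE)
  }
  for (d in list(dur_initial, dur_followup, dur_bhc)) {
    if (length(d) != 2 || d[1] <= 0 || d[2] <= 0) {
      stop("duration models must be (mean, sd) with positive entries",
           call. = FALSE)
    }
  }
  if (mbc_prob < 0 || mbc_prob > 1) {
    stop("mbc_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), fqhc_share = fqhc_share,
    months = as.integer(months),
    delay_probs = delay_probs[want],
    rate_followup = rate_followup, rate_attempt = rate_attempt,
    rate_bhc = rate_bhc,
    dur_initial = unname(dur_initial), dur_followup = unname(dur_followup),
    dur_bhc = unname(dur_bhc),
    mbc_prob = mbc_prob,
    start_date = as.Date(start_date),
    enroll_months = as.integer(enroll_months),
    seed = as.integer(seed)
  ), class = "sim_params")
}

# Mean and SD of a normal(mu, sigma) left-truncated at 1.
.trunc_moments <- function(mu, sigma) {
  a <- (1 - mu) / sigma
  lam <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent normal parameters such that the >=1-truncated distribution has the
# requested mean and SD (the duration model's mean/SD describe the emitted
# minutes, not the parent normal). Falls back to the least-squares best fit
# when the target is not exactly attainable.
.parent_params <- function(mean, sd) {
  obj <- function(par) {
    mm <- .trunc_moments(par[1], exp(par[2]))
    (mm[["mean"]] / mean - 1)^2 + (mm[["sd"]] / sd - 1)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Durations: normal truncated at >= 1 minute (rejection sampling), rounded
# to whole minutes. `parent` comes from .parent_params().
.rdur <- function(n, parent) {
  if (n == 0) return(integer(0))
  x <- stats::rnorm(n, parent[["mu"]], parent[["sigma"]])
  while (any(bad <- x < 1)) {
    x[bad] <- stats::rnorm(sum(bad), parent[["mu"]], parent[["sigma"]])
  }
  as.integer(round(x))
}

.rmbc <- function(n, mbc_prob) {
  complete <- stats::runif(n) < mbc_prob
  ifelse(complete, stats::runif(n, 0.5, 1), stats::runif(n, 0, 0.5))
}

#' Generate a synthetic care-management registry
#'
#' Reproducible given `params$seed`. Each patient gets a randomization date
#' and an engagement delay; pre-engagement months contain only contact
#' attempts, engaged months draw follow-up encounters, BHC consultations and
#' contact attempts from Poisson counts with truncated-normal durations, and
#' each engaging patient has exactly one initial care-manager encounter, in
#' the first engaged month. The first engaged month meets all three CoCM
#' service criteria by construction (the initial encounter documents
#' complete MBC and the month includes at least one BHC consultation, the
#' initial caseload review), so the delay parameter is exactly the number of
#' downstream pre-engagement months. MBC completeness is drawn per follow-up
#' encounter. Contact attempts are emitted with absent minutes, as in the
#' raw registry.
#'
#' @param params A [sim_params()] object.
#' @return List of class `cocm_registry` with `entries`, `patients` and the
#'   generating `params`.
#' @export
simulate_registry <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, {
    n <- params$n_patients
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      clinic_id = NA_character_,
      randomization_date = params$start_date +
        sample.int(params$enroll_months * 30L, n, replace = TRUE) - 1L,
      is_fqhc = stats::runif(n) < params$fqhc_share,
      stringsAsFactors = FALSE
    )
    patients$clinic_id <- ifelse(patients$is_fqhc, "FQHC-1", "NON-FQHC-1")

    delay_levels <- names(params$delay_probs)
    delay <- sample(delay_levels, n, replace = TRUE,
                    prob = params$delay_probs)
    parents <- list(
      initial = .parent_params(params$dur_initial[1], params$dur_initial[2]),
      followup = .parent_params(params$dur_followup[1],
                                params$dur_followup[2]),
      bhc = .parent_params(params$dur_bhc[1], params$dur_bhc[2])
    )

    out <- vector("list", n)
    for (i in seq_len(n)) {
      rand <- patients$randomization_date[i]
      d <- if (delay[i] == "never") params$months else
        as.integer(delay[i])
      rows <- list()
      # months are calendar months (the billing unit); month 1 is the
      # randomization month, clipped to the date-anchored window
      month1 <- as.Date(format(rand, "%Y-%m-01"))
      window_end <- add_months(rand, params$months)
      for (m in seq_len(params$months)) {
        m_start <- max(rand, add_months(month1, m - 1L))
        m_end <- min(add_months(month1, m), window_end)
        span <- as.integer(m_end - m_start)
        rdate <- function(k) m_start + sample.int(span, k, replace = TRUE) - 1L
        engaged <- m > d
        k_att <- stats::rpois(1, params$rate_attempt)
        if (k_att > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            date = rdate(k_att), activity_type = "contact_attempt",
            minutes = NA_real_, mbc_fraction_answered = NA_real_,
            stringsAsFactors = FALSE)
        }
        if (engaged) {
          first_month <- m == d + 1L
          if (first_month) {
            rows[[length(rows) + 1L]] <- data.frame(
              date = rdate(1L), activity_type = "initial_encounter",
              minutes = as.numeric(.rdur(1L, parents$initial)),
              mbc_fraction_answered = stats::runif(1, 0.5, 1),
              stringsAsFactors = FALSE)
          }
          k_fu <- stats::rpois(1, params$rate_followup)
          if (k_fu > 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              date = rdate(k_fu), activity_type = "followup_encounter",
              minutes = as.numeric(.rdur(k_fu, parents$followup)),
              mbc_fraction_answered = .rmbc(k_fu, params$mbc_prob),
              stringsAsFactors = FALSE)
          }
          # the first engaged month always holds the initial caseload review
          k_bhc <- stats::rpois(1, params$rate_bhc) + as.integer(first_month)
          if (k_bhc > 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              date = rdate(k_bhc), activity_type = "bhc_consultation",
              minutes = as.numeric(.rdur(k_bhc, parents$bhc)),
              mbc_fraction_answered = NA_real_,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(rows)) {
        pe <- do.call(rbind, rows)
        pe$patient_id <- patients$patient_id[i]
        pe$clinic_id <- patients$clinic_id[i]
        out[[i]] <- pe
      }
    }
    entries <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    entries <- entries[, c("patient_id", "clinic_id", "date",
                           "activity_type", "minutes",
                           "mbc_fraction_answered")]
    entries <- entries[order(entries$patient_id, entries$date), ,
                       drop = FALSE]
    rownames(entries) <- NULL
    structure(list(entries = entries, patients = patients, params = params),
              class = "cocm_registry")
  })
}

#' @export
print.cocm_registry <- function(x, ...) {
  cat(sprintf("CoCM registry: %d entries, %d patients\n",
              nrow(x$entries), nrow(x$patients)))
  print(table(x$entries$activity_type))
  invisible(x)
}

# Force an integer vector (>= 1 elementwise) to a target sum by proportional
# scaling plus unit adjustments.
.force_total <- function(v, target) {
  stopifnot(length(v) > 0, target >= length(v))
  w <- pmax(1L, as.integer(round(v * target / sum(v))))
  diff <- target - sum(w)
  i <- 1L
  while (diff != 0L) {
    if (diff > 0L) {
      w[i] <- w[i] + 1L
      diff <- diff - 1L
    } else if (w[i] > 1L) {
      w[i] <- w[i] - 1L
      diff <- diff + 1L
    }
    i <- if (i == length(w)) 1L else i + 1L
  }
  w
}

#' Trial-scale fixture registry with forced type-level totals
#'
#' Generates a synthetic registry at trial scale (381 patients) and then
#' forces, by post-hoc scaling of counts and minutes, the per-activity-type
#' totals to the trial's printed registry summary: 10,216 initial-encounter,
#' 45,839 follow-up-encounter and 11,206 BHC-consultation minutes, and
#' exactly 4,747 contact attempts (so that, at the default 5 minutes per
#' attempt, contact minutes are 23,735 and the grand total is 90,996).
#'
#' This is a synthetic stand-in for the trial registry: only the type-level
#' totals are forced; patient-level structure is simulated.
#'
#' @param seed Integer seed.
#' @return A `cocm_registry` list (`entries`, `patients`, `params`).
#' @export
fixture_trial_scale <- function(seed = 1L) {
  targets <- c(initial_encounter = 10216, followup_encounter = 45839,
               bhc_consultation = 11206)
  target_attempts <- 4747L
  reg <- simulate_registry(sim_params(n_patients = 381, seed = seed))
  entries <- reg$entries

  .with_seed(seed + 1L, {
    att <- which(entries$activity_type == "contact_attempt")
    k <- length(att)
    if (k > target_attempts) {
      drop <- sample(att, k - target_attempts)
      entries <- entries[-drop, , drop = FALSE]
    } else if (k < target_attempts) {
      extra <- entries[sample(att, target_attempts - k, replace = TRUE), ,
                       drop = FALSE]
      entries <- rbind(entries, extra)
    }
    for (type in names(targets)) {
      idx <- which(entries$activity_type == type)
      entries$minutes[idx] <- .force_total(entries$minutes[idx],
                                           targets[[type]])
    }
  })
  entries <- entries[order(entries$patient_id, entries$date), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, patients = reg$patients,
                 params = reg$params),
            class = "cocm_registry")
}

#' Estimate generator parameters from a synthetic registry
#'
#' Recovers the duration models (the mean/SD of the emitted minutes, by
#' activity type), the Poisson activity rates and the MBC completion
#' probability from generated data. Engaged months are reconstructed from
#' each patient's initial care-manager encounter (which the generator places
#' in the first engaged month); the guaranteed initial-month caseload review
#' is subtracted before estimating the BHC consultation rate, and MBC
#' completeness is estimated from follow-up encounters only (the initial
#' encounter documents complete MBC by construction).
#'
#' @param registry A `cocm_registry` (or a list with `entries` and
#'   `patients`).
#' @param months Window length the data were generated with.
#' @return List with `dur_initial`, `dur_followup`, `dur_bhc` (each
#'   `c(mean, sd)`), `rate_followup`, `rate_bhc`, `rate_attempt` and
#'   `mbc_prob`.
#' @export
estimate_sim_params <- function(registry, months = 6) {
  entries <- registry$entries
  patients <- registry$patients
  moments <- function(type) {
    x <- entries$minutes[entries$activity_type == type]
    c(mean = mean(x), sd = stats::sd(x))
  }
  first_cm <- tapply(
    ifelse(entries$activity_type == "initial_encounter",
           .month_index(entries$date,
                        patients$randomization_date[
                          match(entries$patient_id, patients$patient_id)]),
           NA_integer_),
    entries$patient_id,
    function(x) if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE)
  )
  n_engaging <- sum(!is.na(first_cm))
  engaged_months <- sum(months - (first_cm - 1L), na.rm = TRUE)
  n_type <- table(entries$activity_type)
  fu <- entries$activity_type == "followup_encounter"
  list(
    dur_initial = moments("initial_encounter"),
    dur_followup = moments("followup_encounter"),
    dur_bhc = moments("bhc_consultation"),
    rate_followup = as.numeric(n_type["followup_encounter"]) / engaged_months,
    rate_bhc = (as.numeric(n_type["bhc_consultation"]) - n_engaging) /
      engaged_months,
    rate_attempt = as.numeric(n_type["contact_attempt"]) /
      (nrow(patients) * months),
    mbc_prob = mean(entries$mbc_fraction_answered[fu] >= 0.5, na.rm = TRUE)
  )
}

#' Write a registry to CSV files
#'
#' @param registry A `cocm_registry`.
#' @param entries_path,patients_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_registry <- function(registry, entries_path, patients_path) {
  e <- registry$entries
  e$date <- format(e$date, "%Y-%m-%d")
  utils::write.csv(e, entries_path, row.names = FALSE, na = "")
  p <- registry$patients
  p$randomization_date <- format(p$randomization_date, "%Y-%m-%d")
  p$is_fqhc <- as.integer(p$is_fqhc)
  utils::write.csv(p, patients_path, row.names = FALSE, na = "")
  invisible(c(entries = entries_path, patients = patients_path))
}
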