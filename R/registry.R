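# Registry data model: read/validate per-activity records, impute contact-attempt
# durations, and aggregate into patient calendar months inside the intervention
# window.

#' Recognized registry activity types
#'
#' The registry records four kinds of care-manager activity: the first
#' face-to-face (or telehealth) encounter with a patient
#' (`initial_encounter`), subsequent encounters (`followup_encounter`),
#' outreach attempts that did not reach the patient (`contact_attempt`), and
#' caseload consultations with the behavioral health consultant
#' (`bhc_consultation`).
#'
#' @return Character vector of the four canonical activity-type labels.
#' @export
activity_types <- function() {
  c("initial_encounter", "followup_encounter", "contact_attempt",
    "bhc_consultation")
}

.cm_encounter_types <- function() c("initial_encounter", "followup_encounter")

#' Default column mapping for registry and patient CSV files
#'
#' Maps canonical field names to the column names expected in input files.
#' Override individual entries to read files with different headers.
#'
#' @param ... Named character overrides, e.g. `date = "activity_date"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
registry_schema <- function(...) {
  schema <- c(
    patient_id = "patient_id",
    clinic_id = "clinic_id",
    date = "date",
    activity_type = "activity_type",
    minutes = "minutes",
    mbc_fraction_answered = "mbc_fraction_answered"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) {
      stop("unknown schema field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    schema[names(dots)] <- dots
  }
  schema
}

# Translate alternative spellings of the activity type to canonical labels.
.normalize_activity_type <- function(x) {
  key <- gsub("[^a-z]", "_", tolower(trimws(x)))
  map <- c(
    initial_encounter = "initial_encounter",
    initial_cm_encounter = "initial_encounter",
    followup_encounter = "followup_encounter",
    follow_up_encounter = "followup_encounter",
    followup_cm_encounter = "followup_encounter",
    contact_attempt = "contact_attempt",
    bhc_consultation = "bhc_consultation",
    bhc_consult = "bhc_consultation"
  )
  out <- unname(map[key])
  out
}

#' Read a care-management registry and its patient table
#'
#' Reads and validates two CSV files: one row per documented activity
#' (registry entries) and one row per patient. Rows that violate the data
#' model (negative minutes, unparseable dates, unknown activity type, minutes
#' recorded on a contact attempt, an MBC fraction outside `[0, 1]` or on a
#' non-encounter row) are rejected with row-level diagnostics rather than
#' failing the whole file.
#'
#' @param entries_path Path to the registry CSV with columns (under the
#'   default schema) `patient_id`, `clinic_id`, `date` (ISO-8601),
#'   `activity_type`, `minutes` (blank allowed only for contact attempts) and
#'   `mbc_fraction_answered` (blank allowed; only meaningful on care-manager
#'   encounters).
#' @param patients_path Path to the patient CSV with columns `patient_id`,
#'   `clinic_id`, `randomization_date` (ISO-8601) and `is_fqhc` (0/1).
#' @param schema Column mapping from [registry_schema()].
#' @return A list of class `cocm_registry` with elements `entries` and
#'   `patients` (data frames). Rejected entry rows, if any, are attached as
#'   attribute `"rejected"` on `entries` with a `reason` column, and a
#'   warning summarizes them.
#' @export
read_registry <- function(entries_path, patients_path,
                          schema = registry_schema()) {
  if (!file.exists(entries_path)) {
    stop("registry file not found: ", entries_path, call. = FALSE)
  }
  if (!file.exists(patients_path)) {
    stop("patients file not found: ", patients_path, call. = FALSE)
  }
  raw <- utils::read.csv(entries_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- schema[c("patient_id", "clinic_id", "date", "activity_type",
                   "minutes")]
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols)) {
    stop("registry file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_mbc_col <- schema[["mbc_fraction_answered"]] %in% names(raw)

  entries <- data.frame(
    patient_id = trimws(raw[[schema[["patient_id"]]]]),
    clinic_id = trimws(raw[[schema[["clinic_id"]]]]),
    date = as.Date(raw[[schema[["date"]]]], format = "%Y-%m-%d"),
    activity_type = .normalize_activity_type(raw[[schema[["activity_type"]]]]),
    minutes = suppressWarnings(as.numeric(raw[[schema[["minutes"]]]])),
    stringsAsFactors = FALSE
  )
  entries$mbc_fraction_answered <- if (has_mbc_col) {
    suppressWarnings(as.numeric(raw[[schema[["mbc_fraction_answered"]]]]))
  } else {
    NA_real_
  }

  blank <- function(x) is.na(x) | x == ""
  minutes_blank <- blank(raw[[schema[["minutes"]]]])
  reason <- rep(NA_character_, nrow(entries))
  flag <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- flag(blank(entries$patient_id), "missing patient_id")
  reason <- flag(is.na(entries$date), "unparseable date")
  reason <- flag(is.na(entries$activity_type), "unknown activity_type")
  is_attempt <- !is.na(entries$activity_type) &
    entries$activity_type == "contact_attempt"
  reason <- flag(!is_attempt & is.na(entries$minutes),
                 "missing or unparseable minutes")
  reason <- flag(is_attempt & !minutes_blank,
                 "contact attempts must not carry minutes")
  reason <- flag(!is.na(entries$minutes) &
                   (entries$minutes < 0 |
                      entries$minutes != floor(entries$minutes)),
                 "minutes must be a nonnegative integer")
  is_cm <- !is.na(entries$activity_type) &
    entries$activity_type %in% .cm_encounter_types()
  reason <- flag(!is_cm & !is.na(entries$mbc_fraction_answered),
                 "mbc_fraction_answered only allowed on care-manager encounters")
  reason <- flag(!is.na(entries$mbc_fraction_answered) &
                   (entries$mbc_fraction_answered < 0 |
                      entries$mbc_fraction_answered > 1),
                 "mbc_fraction_answered outside [0, 1]")

  ok <- is.na(reason)
  rejected <- entries[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$row <- which(!ok)
    rejected$reason <- reason[!ok]
    warning(sprintf("rejected %d registry row(s); see attr(, 'rejected')",
                    nrow(rejected)), call. = FALSE)
  }
  entries <- entries[ok, , drop = FALSE]
  rownames(entries) <- NULL
  attr(entries, "rejected") <- rejected

  praw <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  pneed <- c("patient_id", "clinic_id", "randomization_date", "is_fqhc")
  pmissing <- setdiff(pneed, names(praw))
  if (length(pmissing)) {
    stop("patients file is missing required column(s): ",
         paste(pmissing, collapse = ", "), call. = FALSE)
  }
  patients <- data.frame(
    patient_id = trimws(praw$patient_id),
    clinic_id = trimws(praw$clinic_id),
    randomization_date = as.Date(praw$randomization_date, format = "%Y-%m-%d"),
    is_fqhc = praw$is_fqhc %in% c("1", "TRUE", "true", "T"),
    stringsAsFactors = FALSE
  )
  if (anyNA(patients$randomization_date)) {
    stop("unparseable randomization_date in patients file (rows ",
         paste(which(is.na(patients$randomization_date)), collapse = ", "),
         ")", call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients file", call. = FALSE)
  }

  structure(list(entries = entries, patients = patients),
            class = "cocm_registry")
}

#' Impute durations for contact attempts
#'
#' The registry does not allow time entry on contact attempts, so each is
#' assumed to take a fixed number of minutes (5 by default; 10 is the
#' plausible maximum used in sensitivity analysis).
#'
#' @param entries Registry entry data frame.
#' @param per_attempt_minutes Positive number of minutes per attempt.
#' @return `entries` with all `minutes` present; non-attempt rows unchanged.
#' @export
impute_contact_minutes <- function(entries, per_attempt_minutes = 5) {
  if (!is.numeric(per_attempt_minutes) || length(per_attempt_minutes) != 1 ||
      is.na(per_attempt_minutes) || per_attempt_minutes <= 0) {
    stop("per_attempt_minutes must be a single positive number",
         call. = FALSE)
  }
  idx <- entries$activity_type == "contact_attempt"
  entries$minutes[idx] <- per_attempt_minutes
  entries
}

# Date helpers ---------------------------------------------------------------

#' Add calendar months to a date
#'
#' Clamps the day-of-month (Jan 31 plus one month is Feb 28/29). Used to
#' anchor the intervention window: month `k` of a patient's timeline spans
#' `[add_months(r, k - 1), add_months(r, k))` for randomization date `r`.
#'
#' @param date A `Date` vector.
#' @param k Number of months to add (integer, may be negative).
#' @return A `Date` vector.
#' @export
add_months <- function(date, k) {
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon + k
  y <- total %/% 12L
  m <- total %% 12L
  last_day <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  ld <- last_day[m + 1L]
  leap <- (m == 1L) & ((y + 1900L) %% 4L == 0L &
                         ((y + 1900L) %% 100L != 0L |
                            (y + 1900L) %% 400L == 0L))
  ld[leap] <- 29L
  lt$year <- y
  lt$mon <- m
  lt$mday <- pmin(lt$mday, ld)
  as.Date(lt)
}

.month_key <- function(date) format(date, "%Y-%m")

# 1-based count of calendar months from `from`'s month to `date`'s month.
.month_index <- function(date, from) {
  dl <- as.POSIXlt(date)
  fl <- as.POSIXlt(from)
  (dl$year - fl$year) * 12L + (dl$mon - fl$mon) + 1L
}

#' Aggregate registry entries into patient calendar months
#'
#' Sums documented minutes per patient and calendar month over the
#' intervention window and computes the month-level service-presence flags
#' that the billing rules consume: whether the month had a care-manager
#' encounter, a behavioral-health-consultant consultation, and complete
#' measurement-based care (MBC).
#'
#' Only entries with `randomization_date <= date < end` contribute, where
#' `end` is `randomization_date` plus `window_months` calendar months
#' (half-open, date-anchored) or, with `window_type = "days"`, plus
#' `window_days` days. Months with no in-window entries are not emitted.
#' Entries dated before randomization are rejected with a warning.
#'
#' MBC completeness: a month `has_mbc` when at least one care-manager
#' encounter in it has `mbc_fraction_answered >= mbc_threshold`, or — when
#' the entries carry a precomputed logical `mbc_complete` column — when any
#' encounter has `mbc_complete` true.
#'
#' @param entries Registry entry data frame with all minutes present (run
#'   [impute_contact_minutes()] first).
#' @param patients Patient data frame.
#' @param window_months Length of the intervention window in calendar months.
#' @param mbc_threshold Minimum fraction of MBC items answered for a
#'   measure to count as complete.
#' @param window_type `"calendar"` (default) for a calendar-month window or
#'   `"days"` for a fixed-day window.
#' @param window_days Window length in days when `window_type = "days"`.
#' @return Data frame of class `cocm_months`, one row per patient-month with
#'   in-window activity: ids, `year_month`, `month_index` (1 = month of
#'   randomization), per-type and total minutes, service flags and
#'   `is_fqhc`. Rejected entries are attached as attribute `"rejected"`.
#' @export
aggregate_months <- function(entries, patients, window_months = 6,
                             mbc_threshold = 0.5,
                             window_type = c("calendar", "days"),
                             window_days = 183) {
  window_type <- match.arg(window_type)
  if (anyNA(entries$minutes)) {
    stop("entries contain missing minutes; run impute_contact_minutes() first",
         call. = FALSE)
  }
  unknown <- setdiff(unique(entries$patient_id), patients$patient_id)
  if (length(unknown)) {
    stop("registry entries reference unknown patient_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  pi <- match(entries$patient_id, patients$patient_id)
  rand <- patients$randomization_date[pi]
  end <- if (window_type == "calendar") {
    add_months(rand, window_months)
  } else {
    rand + window_days
  }

  before <- entries$date < rand
  if (any(before)) {
    rej <- entries[before, , drop = FALSE]
    rej$reason <- "entry dated before randomization"
    warning(sprintf("rejected %d entr%s dated before randomization",
                    nrow(rej), if (nrow(rej) == 1) "y" else "ies"),
            call. = FALSE)
  } else {
    rej <- entries[0, , drop = FALSE]
  }
  in_window <- !before & entries$date < end
  e <- entries[in_window, , drop = FALSE]
  pi <- pi[in_window]

  has_complete_col <- "mbc_complete" %in% names(e)
  mbc_ok <- if (has_complete_col) {
    !is.na(e$mbc_complete) & e$mbc_complete
  } else {
    !is.na(e$mbc_fraction_answered) &
      e$mbc_fraction_answered >= mbc_threshold
  }

  key <- paste(e$patient_id, .month_key(e$date), sep = "\r")
  ukey <- !duplicated(key)
  is_cm <- e$activity_type %in% .cm_encounter_types()

  sum_by <- function(x, subset = TRUE) {
    v <- tapply(x * as.numeric(subset), key, sum)
    v[match(key[ukey], names(v))]
  }
  any_by <- function(cond) {
    v <- tapply(cond, key, any)
    as.logical(v[match(key[ukey], names(v))])
  }

  months <- data.frame(
    patient_id = e$patient_id[ukey],
    clinic_id = patients$clinic_id[pi][ukey],
    year_month = .month_key(e$date)[ukey],
    month_index = .month_index(e$date, patients$randomization_date[pi])[ukey],
    minutes_initial = sum_by(e$minutes, e$activity_type == "initial_encounter"),
    minutes_followup = sum_by(e$minutes,
                              e$activity_type == "followup_encounter"),
    minutes_attempt = sum_by(e$minutes, e$activity_type == "contact_attempt"),
    minutes_bhc = sum_by(e$minutes, e$activity_type == "bhc_consultation"),
    has_cm_encounter = any_by(is_cm),
    has_bhc_consult = any_by(e$activity_type == "bhc_consultation"),
    has_mbc = any_by(is_cm & mbc_ok),
    is_fqhc = patients$is_fqhc[pi][ukey],
    stringsAsFactors = FALSE
  )
  months$total_minutes <- months$minutes_initial + months$minutes_followup +
    months$minutes_attempt + months$minutes_bhc
  months$has_registry_entry <- TRUE
  months <- months[order(months$patient_id, months$year_month), , drop = FALSE]
  rownames(months) <- NULL
  attr(months, "rejected") <- rej
  class(months) <- c("cocm_months", "data.frame")
  months
}

#' Write the normalized patient-month table to CSV
#'
#' @param months A `cocm_months` data frame from [aggregate_months()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_months <- function(months, path) {
  utils::write.csv(as.data.frame(months), path, row.names = FALSE)
  invisible(path)
}
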