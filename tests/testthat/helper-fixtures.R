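# Builders for small in-memory fixtures.

# A profiles table (service flags evaluated, engagement computed) for one or
# more patients; `totals` etc. recycle over months.
make_profiles <- function(totals, cm = TRUE, bhc = TRUE, mbc = TRUE,
                          fqhc = FALSE, patient = "P1") {
  n <- length(totals)
  df <- data.frame(
    patient_id = rep_len(patient, n),
    clinic_id = "C1",
    year_month = sprintf("2021-%02d", seq_len(n)),
    month_index = seq_len(n),
    total_minutes = totals,
    has_cm_encounter = rep_len(cm, n),
    has_bhc_consult = rep_len(bhc, n),
    has_mbc = rep_len(mbc, n),
    has_registry_entry = TRUE,
    is_fqhc = rep_len(fqhc, n),
    stringsAsFactors = FALSE
  )
  engagement_timeline(evaluate_services(df))
}

# Billing decisions for a single patient's month sequence.
bill_months <- function(totals, ..., scenario = scenario_config()) {
  process_billing(make_profiles(totals, ...), scenario)
}

# Raw entry rows for registry-level tests.
entry_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r$patient %||% "P1",
               clinic_id = r$clinic %||% "C1",
               date = as.Date(r$date),
               activity_type = r$type,
               minutes = r$minutes %||% NA_real_,
               mbc_fraction_answered = r$mbc %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}

patient_rows <- function(ids = "P1", rand = "2021-01-10", fqhc = FALSE) {
  data.frame(patient_id = ids, clinic_id = "C1",
             randomization_date = as.Date(rep_len(rand, length(ids))),
             is_fqhc = rep_len(fqhc, length(ids)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a registry to temp CSVs for read_registry() tests; returns paths.
write_temp_registry <- function(entries, patients) {
  ep <- tempfile(fileext = ".csv")
  pp <- tempfile(fileext = ".csv")
  e <- entries
  e$date <- format(e$date, "%Y-%m-%d")
  utils::write.csv(e, ep, row.names = FALSE, na = "")
  p <- patients
  p$randomization_date <- format(p$randomization_date, "%Y-%m-%d")
  p$is_fqhc <- as.integer(p$is_fqhc)
  utils::write.csv(p, pp, row.names = FALSE, na = "")
  list(entries = ep, patients = pp)
}

# Small simulated registry shared by scenario-level tests.
small_registry <- function(seed = 42, n = 60) {
  simulate_registry(sim_params(n_patients = n, seed = seed))
}
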