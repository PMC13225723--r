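# Service-requirement evaluation: which patient-months meet the CoCM
# requirements (care-manager encounter + BHC consultation + complete MBC),
# which meet only the general-BHI requirements (encounter + MBC), and which
# months precede the patient's first fully engaged month.

#' Evaluate CoCM and general-BHI service requirements per month
#'
#' CoCM billing codes require, within the calendar month: a care-manager
#' encounter, a behavioral-health-consultant (BHC) caseload consultation,
#' complete measurement-based care, and a registry entry (implied — a month
#' exists only because entries exist). General BHI codes drop the BHC
#' consultation; the continuity-of-care requirement is treated as always met
#' because every patient has an assigned care manager.
#'
#' @param months A `cocm_months` data frame from [aggregate_months()].
#' @return `months` with added columns `cocm_met`, `bhi_met` and
#'   `gap_category` (the set of missing CoCM components as a `"+"`-joined
#'   label over `CM`, `BHC`, `MBC`; `NA` for CoCM-eligible months), of class
#'   `cocm_profiles`.
#' @export
evaluate_services <- function(months) {
  stopifnot(all(c("has_cm_encounter", "has_bhc_consult", "has_mbc") %in%
                  names(months)))
  if (any(months$has_mbc & !months$has_cm_encounter)) {
    stop("invalid months: MBC recorded without a care-manager encounter",
         call. = FALSE)
  }
  months$cocm_met <- months$has_cm_encounter & months$has_bhc_consult &
    months$has_mbc
  months$bhi_met <- months$has_cm_encounter & months$has_mbc
  months$gap_category <- ifelse(
    months$cocm_met, NA_character_,
    mapply(function(cm, bhc, mbc) {
      paste(c("CM", "BHC", "MBC")[c(!cm, !bhc, !mbc)], collapse = "+")
    }, months$has_cm_encounter, months$has_bhc_consult, months$has_mbc)
  )
  class(months) <- unique(c("cocm_profiles", class(months)))
  months
}

#' Classify the service gap of a CoCM-ineligible month
#'
#' Returns which of the three CoCM components (care-manager encounter `CM`,
#' BHC consultation `BHC`, measurement-based care `MBC`) are missing, as a
#' `"+"`-joined label — the taxonomy used to tally why minutes were
#' service-ineligible. Because MBC can only occur during a care-manager
#' encounter, a gap that includes `CM` always includes `MBC` too, so the
#' subsets `{CM}` and `{CM, BHC}` are unreachable.
#'
#' @param has_cm_encounter,has_bhc_consult,has_mbc Logical service flags for
#'   one month.
#' @return Character label, e.g. `"BHC"` or `"CM+BHC+MBC"`.
#' @export
classify_service_gap <- function(has_cm_encounter, has_bhc_consult, has_mbc) {
  if (has_cm_encounter && has_bhc_consult && has_mbc) {
    stop("classify_service_gap() called on a CoCM-eligible month",
         call. = FALSE)
  }
  if (has_mbc && !has_cm_encounter) {
    stop("invalid month: MBC without a care-manager encounter", call. = FALSE)
  }
  paste(c("CM", "BHC", "MBC")[c(!has_cm_encounter, !has_bhc_consult,
                                !has_mbc)],
        collapse = "+")
}

#' Flag pre-engagement months
#'
#' A patient's engagement month is the first calendar month in which all
#' three CoCM service requirements were met. Months strictly before it (all
#' months, for patients who never engage) are pre-engagement: outreach time
#' whose unbillable minutes are tallied separately.
#'
#' @param profiles A `cocm_profiles` data frame from [evaluate_services()].
#' @return `profiles` with added columns `first_engaged_index` (the
#'   patient's first CoCM-eligible `month_index`; `NA` if never) and logical
#'   `pre_engagement`.
#' @export
engagement_timeline <- function(profiles) {
  stopifnot(all(c("patient_id", "month_index", "cocm_met") %in%
                  names(profiles)))
  first_idx <- tapply(
    ifelse(profiles$cocm_met, profiles$month_index, NA_integer_),
    profiles$patient_id,
    function(x) if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE)
  )
  profiles$first_engaged_index <-
    as.integer(first_idx[match(profiles$patient_id, names(first_idx))])
  profiles$pre_engagement <- is.na(profiles$first_engaged_index) |
    profiles$month_index < profiles$first_engaged_index
  profiles
}

#' Write the per-month eligibility table to CSV
#'
#' @param profiles A `cocm_profiles` data frame, ideally after
#'   [engagement_timeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eligibility <- function(profiles, path) {
  cols <- intersect(
    c("patient_id", "year_month", "month_index", "total_minutes",
      "cocm_met", "bhi_met", "gap_category", "pre_engagement"),
    names(profiles)
  )
  utils::write.csv(as.data.frame(profiles)[, cols], path, row.names = FALSE)
  invisible(path)
}
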