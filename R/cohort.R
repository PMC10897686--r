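#' Index date: first qualifying antidepressant prescription
#'
#' The index date anchoring a patient's follow-up is the earliest
#' antidepressant issue date on or after the study start and no later than
#' the study end. Prescriptions for augmentation agents or unknown drugs
#' do not qualify.
#'
#' @param scripts Prescription records for one patient
#'   (see [read_prescriptions()]).
#' @param cfg A [study_config()].
#' @return A `Date`, or `NA` if the patient has no qualifying script.
#' @export
compute_index_date <- function(scripts, cfg = study_config()) {
  if (nrow(scripts) == 0L) return(as.Date(NA))
  ok <- scripts$drug_role == "antidepressant" &
    scripts$issue_date >= cfg$study_start &
    scripts$issue_date <= cfg$study_end
  if (!any(ok)) return(as.Date(NA))
  min(scripts$issue_date[ok])
}

#' Screen one patient's events for exclusion diagnoses
#'
#' A patient is excluded if any exclusion-category code (bipolar disorder,
#' dementia, mania, psychosis, schizophrenia or schizoaffective disorder)
#' is recorded on or after the exclusion look-back start (2010-01-01 by
#' default).
#'
#' @param events Clinical events for one patient.
#' @param cfg A [study_config()].
#' @return Character vector of exclusion reasons (empty if none).
#' @export
check_exclusions <- function(events, cfg = study_config()) {
  if (nrow(events) == 0L) return(character())
  hit <- events$category == "exclusion" &
    events$event_date >= cfg$exclusion_lookback_start
  if (any(hit)) "exclusion_code" else character()
}

#' Build the analyzable cohort
#'
#' Applies the eligibility rules to every patient appearing in any input:
#' an index date must exist (an antidepressant script within the study
#' window), the patient must be an adult (>= 18 years) at the index date,
#' a depression code must be recorded at any time up to the study end
#' (codes recorded after the first prescription still qualify), and no
#' exclusion diagnosis may be recorded from the exclusion look-back start
#' onwards.
#'
#' @param prescriptions All prescription records.
#' @param events All clinical events.
#' @param demographics Demographics table (see [read_demographics()]).
#' @param cfg A [study_config()].
#' @return A data frame with one row per patient: `patient_id`,
#'   `index_date`, `eligible`, `exclusion_reasons` (";"-joined),
#'   `age_unresolved` (TRUE when date of birth was missing).
#' @export
build_cohort <- function(prescriptions, events, demographics,
                         cfg = study_config()) {
  ids <- sort(unique(c(prescriptions$patient_id, events$patient_id,
                       demographics$patient_id)))
  rx_by <- split(seq_len(nrow(prescriptions)), prescriptions$patient_id)
  ev_by <- split(seq_len(nrow(events)), events$patient_id)
  dob <- demographics$date_of_birth[match(ids, demographics$patient_id)]

  index_date <- as.Date(rep(NA, length(ids)))
  eligible <- logical(length(ids))
  reasons <- character(length(ids))
  age_unresolved <- logical(length(ids))

  for (i in seq_along(ids)) {
    pid <- ids[i]
    rx <- prescriptions[rx_by[[pid]] %||% integer(), , drop = FALSE]
    ev <- events[ev_by[[pid]] %||% integer(), , drop = FALSE]
    why <- character()

    idx <- compute_index_date(rx, cfg)
    index_date[i] <- idx
    if (is.na(idx)) why <- c(why, "no_antidepressant_in_window")

    has_dep <- nrow(ev) > 0L && any(ev$category == "depression" &
                                      ev$event_date <= cfg$study_end)
    if (!has_dep) why <- c(why, "no_depression_code")

    if (is.na(dob[i])) {
      # adulthood cannot be established without a date of birth
      age_unresolved[i] <- TRUE
      why <- c(why, "under_18")
    } else if (!is.na(idx) && age_at(dob[i], idx) < 18L) {
      why <- c(why, "under_18")
    }
    why <- c(why, check_exclusions(ev, cfg))

    eligible[i] <- length(why) == 0L
    reasons[i] <- paste(why, collapse = ";")
  }
  if (any(age_unresolved)) {
    warning(sum(age_unresolved),
            " patient(s) with missing date of birth marked ineligible")
  }
  data.frame(
    patient_id = ids,
    index_date = index_date,
    eligible = eligible,
    exclusion_reasons = reasons,
    age_unresolved = age_unresolved,
    stringsAsFactors = FALSE
  )
}
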