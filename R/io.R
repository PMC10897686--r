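#' Read prescription records
#'
#' Reads a delimited prescriptions file (columns `patient_id`,
#' `drug_code`, `issue_date`, `daily_dose`, `supply_days`), maps drug
#' codes through the dictionary, imputes missing supply lengths with the
#' configured default (30 days by convention, the typical script length),
#' and sorts by patient and issue date. Rows with an unparseable date or a
#' blank patient id are rejected with a diagnostic; codes absent from the
#' dictionary are kept with `drug_role = "other"`.
#'
#' @param path CSV path.
#' @param dict A [code_dictionary][load_code_dictionary].
#' @param cfg A [study_config()].
#' @return A data frame of prescription records with attributes
#'   `n_rejected` and `rejected_rows` documenting dropped input rows.
#' @export
read_prescriptions <- function(path, dict, cfg = study_config()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "drug_code", "issue_date", "daily_dose",
                "supply_days")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("prescriptions file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dates <- as_date_strict(raw$issue_date)
  bad_date <- is.na(dates)
  bad_id <- is.na(raw$patient_id) | trimws(raw$patient_id) == ""
  reject <- bad_date | bad_id
  if (any(reject)) {
    warning(sum(reject), " prescription row(s) rejected (rows ",
            paste(utils::head(which(reject), 10L), collapse = ", "),
            if (sum(reject) > 10L) ", ..." else "", ")")
  }
  keep <- raw[!reject, , drop = FALSE]
  dates <- dates[!reject]

  supply <- suppressWarnings(as.integer(keep$supply_days))
  supply[is.na(supply)] <- cfg$default_supply_days
  if (any(supply < 1L)) stop("supply_days must be >= 1")
  dose <- suppressWarnings(as.numeric(keep$daily_dose))
  if (any(!is.na(dose) & dose < 0)) stop("daily_dose must be nonnegative")

  drug <- dict_drug_match(dict, keep$drug_code)
  unknown <- unique(keep$drug_code[drug$drug_role == "other"])
  if (length(unknown) > 0L) {
    message("prescription drug code(s) not in dictionary, tagged 'other': ",
            paste(unknown, collapse = ", "))
  }
  out <- data.frame(
    patient_id = keep$patient_id,
    drug_code = keep$drug_code,
    ingredient = ifelse(is.na(drug$ingredient), keep$drug_code,
                        drug$ingredient),
    drug_role = drug$drug_role,
    agent_class = drug$agent_class,
    issue_date = dates,
    daily_dose = dose,
    supply_days = supply,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$issue_date, out$ingredient), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(reject)
  attr(out, "rejected_rows") <- which(reject)
  out
}

#' Read coded clinical events
#'
#' Columns: `patient_id`, `code`, `code_system` (`read_v2` or `icd10`),
#' `event_date`. Categories (depression, exclusion, comorbidity,
#' suicidality, mhs_referral, mhs_contact, assessment) are assigned solely
#' from the dictionary; unknown codes become category `"other"` with a
#' warning. Rows with an invalid code system or unparseable date are
#' rejected.
#'
#' @inheritParams read_prescriptions
#' @return A data frame of clinical events sorted by patient and date.
#' @export
read_clinical_events <- function(path, dict) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "code", "code_system", "event_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("clinical events file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(data.frame(patient_id = character(), code = character(),
                      code_system = character(),
                      category = character(),
                      event_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  dates <- as_date_strict(raw$event_date)
  bad_system <- !(raw$code_system %in% c("read_v2", "icd10"))
  bad_id <- is.na(raw$patient_id) | trimws(raw$patient_id) == ""
  reject <- is.na(dates) | bad_system | bad_id
  if (any(reject)) {
    warning(sum(reject), " clinical event row(s) rejected")
  }
  keep <- raw[!reject, , drop = FALSE]
  category <- dict_clinical_match(dict, keep$code)
  unknown <- unique(keep$code[category == "other"])
  if (length(unknown) > 0L) {
    warning("clinical code(s) not in dictionary, tagged 'other': ",
            paste(unknown, collapse = ", "))
  }
  out <- data.frame(
    patient_id = keep$patient_id,
    code = keep$code,
    code_system = keep$code_system,
    category = category,
    event_date = dates[!reject],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$event_date, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(reject)
  out
}

#' Read secondary-care contact events
#'
#' Columns: `patient_id`, `contact_date`, `setting` (free text, e.g.
#' outpatient, inpatient, a_and_e, crisis, liaison, community, home).
#' Any recorded contact counts towards the mental-health-services contact
#' subgroup, whether or not a primary-care referral code exists.
#'
#' @param path CSV path.
#' @return A data frame sorted by patient and date.
#' @export
read_contacts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "contact_date", "setting")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("contacts file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dates <- as_date_strict(raw$contact_date)
  reject <- is.na(dates) | is.na(raw$patient_id) |
    trimws(raw$patient_id) == ""
  if (any(reject)) warning(sum(reject), " contact row(s) rejected")
  out <- data.frame(
    patient_id = raw$patient_id[!reject],
    contact_date = dates[!reject],
    setting = raw$setting[!reject],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$contact_date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read patient demographics
#'
#' Columns: `patient_id`, `date_of_birth`, `gender`. Presence in this
#' table stands in for GP registration.
#'
#' @param path CSV path.
#' @return A data frame, one row per patient.
#' @export
read_demographics <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "date_of_birth", "gender")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("demographics file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(duplicated(raw$patient_id))) {
    stop("duplicate patient_id in demographics")
  }
  data.frame(
    patient_id = raw$patient_id,
    date_of_birth = as_date_strict(raw$date_of_birth),
    gender = raw$gender,
    stringsAsFactors = FALSE
  )
}

#' Write a record table as CSV
#'
#' Dates are formatted as ISO `YYYY-MM-DD` so that a write/read cycle
#' through the package readers is the identity on all fields.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  out <- x
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
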