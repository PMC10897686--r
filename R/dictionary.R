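CLINICAL_CATEGORIES <- c("depression", "exclusion", "comorbidity",
                         "suicidality", "mhs_referral", "mhs_contact",
                         "assessment")
DRUG_ROLES <- c("antidepressant", "augmentation_agent")
AUGMENTATION_CLASSES <- c("lithium", "antipsychotic", "thyroxine",
                          "tri_iodothyronine", "anticonvulsant")

#' Load a code dictionary
#'
#' A code dictionary maps raw source codes to either a drug (an
#' antidepressant ingredient or an augmentation agent, with its class and
#' optional minimum effective daily dose) or a clinical-event category
#' (depression, exclusion, comorbidity, suicidality, secondary
#' mental-health referral/contact, assessment). Dictionaries are data, not
#' code: the shipped default (see [default_code_dictionary()]) can be
#' replaced by any file with the same columns.
#'
#' Expected columns: `code`, `name`, `role` (for drug rows), `category`
#' (for clinical rows), `agent_class` (augmentation agents only; one of
#' lithium, antipsychotic, thyroxine, tri_iodothyronine, anticonvulsant)
#' and `min_daily_dose` (optional, antidepressants only).
#'
#' @param path Path to a dictionary CSV.
#' @return An object of class `code_dictionary` with components `drugs`
#'   and `clinical`.
#' @export
load_code_dictionary <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("code", "name", "role", "category")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("code dictionary is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"agent_class" %in% names(raw)) raw$agent_class <- ""
  if (!"min_daily_dose" %in% names(raw)) raw$min_daily_dose <- ""
  if (nrow(raw) == 0L) {
    warning("empty code dictionary loaded from ", path)
    return(new_code_dictionary(
      drugs = data.frame(code = character(), ingredient = character(),
                         drug_role = character(), agent_class = character(),
                         min_daily_dose = numeric(),
                         stringsAsFactors = FALSE),
      clinical = data.frame(code = character(), category = character(),
                            stringsAsFactors = FALSE)
    ))
  }
  raw$code <- trimws(raw$code)
  raw$role <- trimws(raw$role)
  raw$category <- trimws(raw$category)

  is_drug <- raw$role != ""
  is_clin <- raw$category != ""
  if (any(is_drug & is_clin)) {
    stop("code(s) mapped to both a drug role and a clinical category: ",
         paste(raw$code[is_drug & is_clin], collapse = ", "))
  }
  if (any(!is_drug & !is_clin)) {
    stop("code(s) with neither role nor category: ",
         paste(raw$code[!is_drug & !is_clin], collapse = ", "))
  }
  bad_role <- is_drug & !(raw$role %in% DRUG_ROLES)
  if (any(bad_role)) {
    stop("unknown drug role(s): ",
         paste(unique(raw$role[bad_role]), collapse = ", "))
  }
  bad_cat <- is_clin & !(raw$category %in% CLINICAL_CATEGORIES)
  if (any(bad_cat)) {
    stop("unknown clinical categor(ies): ",
         paste(unique(raw$category[bad_cat]), collapse = ", "))
  }
  # one code, one meaning
  dup <- unique(raw$code[duplicated(raw$code)])
  for (code in dup) {
    rows <- raw[raw$code == code, c("name", "role", "category", "agent_class")]
    if (nrow(unique(rows)) > 1L) {
      stop("code '", code, "' has conflicting dictionary mappings")
    }
  }
  raw <- raw[!duplicated(raw$code), , drop = FALSE]

  drugs <- raw[raw$role != "", , drop = FALSE]
  drugs$drug_role <- drugs$role
  is_aug <- drugs$drug_role == "augmentation_agent"
  bad_agent <- is_aug & !(drugs$agent_class %in% AUGMENTATION_CLASSES)
  if (any(bad_agent)) {
    stop("augmentation agent(s) with missing/unknown class: ",
         paste(drugs$code[bad_agent], collapse = ", "))
  }
  drugs_df <- data.frame(
    code = drugs$code,
    ingredient = drugs$name,
    drug_role = drugs$drug_role,
    agent_class = ifelse(is_aug, drugs$agent_class, NA_character_),
    min_daily_dose = suppressWarnings(as.numeric(drugs$min_daily_dose)),
    stringsAsFactors = FALSE
  )
  clinical_df <- data.frame(
    code = raw$code[raw$category != ""],
    category = raw$category[raw$category != ""],
    stringsAsFactors = FALSE
  )
  new_code_dictionary(drugs_df, clinical_df)
}

new_code_dictionary <- function(drugs, clinical) {
  structure(list(drugs = drugs, clinical = clinical),
            class = "code_dictionary")
}

#' The shipped default code dictionary
#'
#' A small synthetic vocabulary: eight antidepressant ingredients with
#' minimum effective daily doses, augmentation agents covering the five
#' classes of interest (lithium, antipsychotics, thyroxine,
#' tri-iodothyronine, anticonvulsants), and clinical codes for depression,
#' the exclusion diagnoses, common comorbidities, suicidality,
#' secondary mental-health referral/contact and assessment instruments.
#' Codes are synthetic stand-ins, not real Read v2 or ICD-10 codes.
#'
#' @return A `code_dictionary`.
#' @export
default_code_dictionary <- function() {
  path <- system.file("extdata", "default_code_dictionary.csv",
                      package = "rxpathways", mustWork = TRUE)
  load_code_dictionary(path)
}

#' @export
print.code_dictionary <- function(x, ...) {
  cat(sprintf("Code dictionary: %d drug codes (%d antidepressants, %d augmentation agents), %d clinical codes\n",
              nrow(x$drugs),
              sum(x$drugs$drug_role == "antidepressant"),
              sum(x$drugs$drug_role == "augmentation_agent"),
              nrow(x$clinical)))
  invisible(x)
}

# code -> row lookups used by the readers
dict_drug_match <- function(dict, codes) {
  idx <- match(codes, dict$drugs$code)
  data.frame(
    ingredient = dict$drugs$ingredient[idx],
    drug_role = ifelse(is.na(idx), "other", dict$drugs$drug_role[idx]),
    agent_class = dict$drugs$agent_class[idx],
    min_daily_dose = dict$drugs$min_daily_dose[idx],
    stringsAsFactors = FALSE
  )
}

dict_clinical_match <- function(dict, codes) {
  idx <- match(codes, dict$clinical$code)
  ifelse(is.na(idx), "other", dict$clinical$category[idx])
}

# ingredient -> code (used by the synthetic generator so its files read
# back through the same dictionary)
dict_code_for_ingredient <- function(dict, ingredients) {
  idx <- match(ingredients, dict$drugs$ingredient)
  if (anyNA(idx)) {
    stop("ingredient(s) not in dictionary: ",
         paste(ingredients[is.na(idx)], collapse = ", "))
  }
  dict$drugs$code[idx]
}

dict_code_for_category <- function(dict, categories) {
  idx <- match(categories, dict$clinical$category)
  if (anyNA(idx)) {
    stop("categor(ies) not in dictionary: ",
         paste(categories[is.na(idx)], collapse = ", "))
  }
  dict$clinical$code[idx]
}
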