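# Shared fixture builders. Scripts are specified in day offsets from a
# base date well inside the study window so boundary tests are unaffected
# by censoring.

BASE_DATE <- as.Date("2016-03-01")

test_dict <- function() default_code_dictionary()

# enriched prescription rows as the reader would produce them
rx_rows <- function(patient_id, ingredient, days, supply = 30L,
                    dose = NULL, base = BASE_DATE,
                    dict = test_dict()) {
  idx <- match(ingredient, dict$drugs$ingredient)
  role <- dict$drugs$drug_role[idx]
  if (is.null(dose)) dose <- dict$drugs$min_daily_dose[idx]
  n <- length(days)
  data.frame(
    patient_id = rep_len(patient_id, n),
    drug_code = rep_len(dict$drugs$code[idx], n),
    ingredient = rep_len(ingredient, n),
    drug_role = rep_len(ifelse(is.na(role), "other", role), n),
    agent_class = rep_len(dict$drugs$agent_class[idx], n),
    issue_date = base + days,
    daily_dose = rep_len(dose, n),
    supply_days = rep_len(as.integer(supply), n),
    stringsAsFactors = FALSE
  )
}

# one patient's sequences straight from scripts
seqs_of <- function(scripts, cfg = study_config()) {
  derive_sequences(expand_and_merge_coverage(scripts, cfg), cfg)
}

event_rows <- function(patient_id, category, days,
                       base = BASE_DATE, dict = test_dict()) {
  code <- dict$clinical$code[match(category, dict$clinical$category)]
  data.frame(patient_id = patient_id, code = code, code_system = "read_v2",
             category = category, event_date = base + days,
             stringsAsFactors = FALSE)
}

# random small prescription set for oracle comparisons: up to max_scripts
# scripts over a few drugs, mixed supplies and gaps
random_scripts <- function(patient_id, max_scripts = 6L,
                           drugs = c("citalopram", "sertraline",
                                     "mirtazapine")) {
  k <- sample(seq_len(max_scripts), 1L)
  rx_rows(patient_id,
          ingredient = sample(drugs, k, replace = TRUE),
          days = sort(sample(0:600, k)),
          supply = sample(c(14L, 30L, 30L, 60L), k, replace = TRUE),
          dose = sample(c(NA, 20, 40), k, replace = TRUE))
}
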