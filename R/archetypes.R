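# Hand-constructed boundary fixtures: one patient per rule edge, with the
# classification each one must receive worked out from the definitions.
# Used by the test suite and available to users as worked examples.

#' Archetype patients at every rule boundary
#'
#' Emits a bundle of hand-constructed patients, one per outcome-rule edge:
#' responses at 90 vs 89 days, remission by duration at 180 vs 179 days,
#' remission by gap at 61 vs a blocked 30-day gap, relapses at gaps of 60
#' and 180 days versus none at 59 and 181, combinations at 45 vs 44 days,
#' augmentation overlaps at 45 vs 44 days, a clean two-failed-line
#' resistant patient (plus an underdosed variant that stays
#' non-resistant), an episode-break non-resistant patient, an immediate
#' switch, and a resumption. Each patient carries a depression code and
#' adult demographics so the bundle passes cohort screening unchanged.
#'
#' @param dict Code dictionary used to emit drug codes.
#' @return A list with `prescriptions`, `events`, `contacts`,
#'   `demographics` (reader-format data frames) and `expected`, one row
#'   per archetype giving the group, line count and event counts the
#'   classifier must produce.
#' @export
generate_archetypes <- function(dict = default_code_dictionary()) {
  base <- as.Date("2016-03-01")
  rx <- list(); expected <- list()
  sc <- function(pid, drug, days, supply = 30L, dose = NULL) {
    if (is.null(dose)) {
      dose <- dict$drugs$min_daily_dose[match(drug, dict$drugs$ingredient)]
    }
    data.frame(patient_id = pid,
               drug_code = dict_code_for_ingredient(dict, rep(drug, length(days))),
               issue_date = base + days,
               daily_dose = rep(dose, length(days)),
               supply_days = supply, stringsAsFactors = FALSE)
  }
  expect <- function(pid, archetype, group, lines, response = 0L,
                     remission = 0L, relapse = 0L, switch = 0L,
                     combination = 0L, resumption = 0L, augmentation = 0L,
                     failures = 0L) {
    data.frame(patient_id = pid, archetype = archetype, group = group,
               lines = lines, n_response = response, n_remission = remission,
               n_relapse = relapse, n_switch = switch,
               n_combination = combination, n_resumption = resumption,
               n_augmentation = augmentation, n_failures = failures,
               stringsAsFactors = FALSE)
  }
  add <- function(scripts, exp_row) {
    rx[[length(rx) + 1L]] <<- scripts
    expected[[length(expected) + 1L]] <<- exp_row
  }

  # -- response duration boundary -----------------------------------------
  # coverage [0, 90): response; [0, 89): one day short
  add(sc("AR01", "citalopram", c(0, 30, 60)),
      expect("AR01", "response_90d", "MDD", 1L, response = 1L,
             remission = 1L))                      # remission via gap clause
  add(sc("AR02", "citalopram", c(0, 30, 59)),
      expect("AR02", "response_89d", "MDD", 1L, failures = 1L))

  # -- relapse window boundaries (inclusive 60 and 180) -------------------
  # responding 100-day sequence, then a responding replacement drug
  add(rbind(sc("AR03", "citalopram", c(0, 30, 70)),
            sc("AR03", "sertraline", c(160, 190, 220, 250))),
      expect("AR03", "relapse_gap_60", "MDD", 1L, response = 2L,
             remission = 2L, relapse = 1L, switch = 1L, failures = 1L))
  add(rbind(sc("AR04", "citalopram", c(0, 30, 70)),
            sc("AR04", "sertraline", c(159, 189, 219, 249))),
      expect("AR04", "no_relapse_59", "MDD", 2L, response = 2L,
             remission = 1L, switch = 1L, failures = 1L))
  add(rbind(sc("AR05", "citalopram", c(0, 30, 70)),
            sc("AR05", "sertraline", c(280, 310, 340, 370))),
      expect("AR05", "relapse_gap_180", "MDD", 1L, response = 2L,
             remission = 2L, relapse = 1L, switch = 1L, failures = 1L))
  # same drug after 181 days: resumption, not relapse
  add(rbind(sc("AR06", "citalopram", c(0, 30, 70)),
            sc("AR06", "citalopram", c(281, 311, 341, 371))),
      expect("AR06", "no_relapse_181", "MDD", 1L, response = 2L,
             remission = 2L, resumption = 1L))

  # -- combination duration boundary (45 vs 44 days of enlarged regimen) --
  add(rbind(sc("AR07", "citalopram", seq(0, 170, by = 30)),
            sc("AR07", "mirtazapine", seq(60, 170, by = 30))),
      expect("AR07", "combination_long", "MDD", 2L, response = 1L,
             remission = 1L, combination = 1L, failures = 1L))
  # both failed short lines: enlarged regimen held exactly 45 days
  add(rbind(sc("AR08", "citalopram", c(0, 30, 75)),
            sc("AR08", "mirtazapine", c(60, 75))),
      expect("AR08", "combination_45", "TRD", 2L, combination = 1L,
             failures = 2L))
  # held 44 days: no combination, no second line, no resistance
  add(rbind(sc("AR09", "citalopram", c(0, 30, 74)),
            sc("AR09", "mirtazapine", c(60, 74))),
      expect("AR09", "combination_44", "MDD", 1L, failures = 2L))

  # -- augmentation overlap boundary --------------------------------------
  add(rbind(sc("AR10", "citalopram", c(0, 30, 60, 90)),
            sc("AR10", "lithium", 10, supply = 45L)),
      expect("AR10", "augmentation_45", "MDD", 1L, response = 1L,
             remission = 1L, augmentation = 1L, failures = 1L))
  add(rbind(sc("AR11", "citalopram", c(0, 30, 60, 90)),
            sc("AR11", "lithium", 10, supply = 44L)),
      expect("AR11", "augmentation_44", "MDD", 1L, response = 1L,
             remission = 1L))

  # -- resistance: two adequate failed distinct lines ---------------------
  add(rbind(sc("AR12", "sertraline", c(0, 30)),
            sc("AR12", "citalopram", c(70, 100))),
      expect("AR12", "trd_two_lines", "TRD", 2L, switch = 1L,
             failures = 2L))
  # underdosed first line: not adequate, so not resistant
  add(rbind(sc("AR13", "citalopram", c(0, 30), dose = 10),
            sc("AR13", "sertraline", c(70, 100))),
      expect("AR13", "trd_low_dose_excluded", "MDD", 2L, switch = 1L,
             failures = 2L))
  # two failed lines in different episodes (200-day treatment-free gap)
  add(rbind(sc("AR14", "citalopram", c(0, 30)),
            sc("AR14", "sertraline", c(260, 290))),
      expect("AR14", "episode_break_non_trd", "MDD", 1L, failures = 2L))
  # failure by augmentation despite response, after an earlier failed line
  add(rbind(sc("AR15", "citalopram", c(0, 30)),
            sc("AR15", "sertraline", c(65, 95, 125, 155)),
            sc("AR15", "lithium", 70, supply = 50L)),
      expect("AR15", "trd_fail_plus_augmented_response", "TRD", 2L,
             response = 1L, remission = 1L, switch = 1L, augmentation = 1L,
             failures = 2L))

  # -- switching and resumption -------------------------------------------
  add(rbind(sc("AR16", "citalopram", c(0, 20)),
            sc("AR16", "sertraline", c(50, 80, 110, 140))),
      expect("AR16", "immediate_switch", "MDD", 2L, response = 1L,
             remission = 1L, switch = 1L, failures = 1L))
  add(rbind(sc("AR17", "fluoxetine", c(0, 40)),
            sc("AR17", "fluoxetine", c(260, 300))),
      expect("AR17", "resumption_after_break", "MDD", 1L, resumption = 1L,
             failures = 2L))

  # -- remission boundaries ------------------------------------------------
  # duration clause at exactly 180 days, gap clause blocked by a switch
  add(rbind(sc("AR18", "citalopram", seq(0, 150, by = 30)),
            sc("AR18", "sertraline", c(210, 240, 270, 300))),
      expect("AR18", "remission_duration_180", "MDD", 1L, response = 2L,
             remission = 2L, switch = 1L, failures = 1L))
  add(rbind(sc("AR19", "citalopram", c(seq(0, 120, by = 30), 149)),
            sc("AR19", "sertraline", c(209, 239, 269, 299))),
      expect("AR19", "remission_duration_179", "MDD", 2L, response = 2L,
             remission = 1L, switch = 1L, failures = 1L))
  # gap clause: next coverage 61 days after end fires it (and a relapse)
  add(rbind(sc("AR20", "citalopram", c(0, 30, 70)),
            sc("AR20", "sertraline", c(161, 191, 221, 251))),
      expect("AR20", "remission_gap_61", "MDD", 1L, response = 2L,
             remission = 2L, relapse = 1L, switch = 1L, failures = 1L))
  # next coverage 30 days after end blocks it
  add(rbind(sc("AR21", "citalopram", c(0, 30, 70)),
            sc("AR21", "sertraline", c(130, 160, 190, 220))),
      expect("AR21", "remission_gap_blocked_30", "MDD", 2L, response = 2L,
             remission = 1L, switch = 1L, failures = 1L))

  prescriptions <- do.call(rbind, rx)
  rownames(prescriptions) <- NULL
  expected <- do.call(rbind, expected)
  rownames(expected) <- NULL
  ids <- unique(prescriptions$patient_id)
  dep_code <- dict$clinical$code[dict$clinical$category == "depression"][1]
  events <- data.frame(
    patient_id = ids, code = dep_code, code_system = "read_v2",
    event_date = as.Date("2014-06-01"), stringsAsFactors = FALSE
  )
  demographics <- data.frame(
    patient_id = ids, date_of_birth = as.Date("1980-01-15"),
    gender = "F", stringsAsFactors = FALSE
  )
  contacts <- data.frame(patient_id = character(),
                         contact_date = as.Date(character()),
                         setting = character(), stringsAsFactors = FALSE)
  list(prescriptions = prescriptions, events = events, contacts = contacts,
       demographics = demographics, expected = expected)
}
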