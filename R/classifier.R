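# Outcome rules over treatment sequences.
#
# All rules work on the per-patient sequence table produced by
# derive_sequences(): response and remission are properties of a single
# sequence (plus what follows it), relapse and the transition types are
# properties of consecutive sequence pairs, and the patient-level
# classification (MDD vs TRD, lines of therapy) aggregates over episodes.

#' Detect treatment response
#'
#' A sequence is a response when a single constant regimen is sustained
#' for at least 90 days with no change other than dose. Regimen constancy
#' is guaranteed by sequence construction; dose changes are ignored.
#'
#' @param seqs Sequence table for one patient ([derive_sequences()]).
#' @param cfg A [study_config()].
#' @return Logical vector, one element per sequence.
#' @export
detect_response <- function(seqs, cfg = study_config()) {
  seqs$duration_days >= cfg$response_min_days
}

#' Detect remission
#'
#' A sequence marks remission when it is a response lasting at least 180
#' days, or a response of at least 90 days followed by 60 days with no
#' antidepressant coverage beginning. The drug-free window is half-open: a
#' sequence starting exactly 60 days after the end does not block
#' remission. The gap clause is only evaluated when the full 60-day window
#' is observable before the study end (an ongoing treatment censored at
#' the study boundary is not a remission by discontinuation).
#'
#' @inheritParams detect_response
#' @return Logical vector per sequence, with attribute `"clause"` naming
#'   which clause fired (`"duration"`, `"gap"` or `NA`).
#' @export
detect_remission <- function(seqs, cfg = study_config()) {
  n <- nrow(seqs)
  if (n == 0L) return(logical())
  gap_next <- c(as.integer(seqs$start[-1] - seqs$end[-n]), NA_integer_)
  by_duration <- seqs$duration_days >= cfg$remission_response_days
  observable <- as.integer(cfg$study_end + 1L - seqs$end) >=
    cfg$remission_gap_days
  drug_free <- is.na(gap_next) | gap_next >= cfg$remission_gap_days
  by_gap <- seqs$duration_days >= cfg$response_min_days & observable &
    drug_free
  out <- by_duration | by_gap
  attr(out, "clause") <- ifelse(by_duration, "duration",
                                ifelse(by_gap, "gap", NA_character_))
  out
}

#' Detect relapse
#'
#' A relapse is a new treatment sequence starting 60 to 180 days
#' (inclusive at both ends) after the end of a sequence that had resulted
#' in a response.
#'
#' @inheritParams detect_response
#' @return Logical vector per sequence; element j is TRUE when sequence j
#'   is a relapse relative to sequence j-1.
#' @export
detect_relapse <- function(seqs, cfg = study_config()) {
  n <- nrow(seqs)
  if (n == 0L) return(logical())
  resp <- detect_response(seqs, cfg)
  out <- logical(n)
  if (n == 1L) return(out)
  gap <- as.integer(seqs$start[-1] - seqs$end[-n])
  rw <- cfg$relapse_window_days
  out[-1] <- resp[-n] & gap >= rw[1] & gap <= rw[2]
  out
}

#' Classify the transition between two consecutive sequences
#'
#' Transition types, in precedence order:
#' * `combination`: the new regimen strictly contains the old one and is
#'   sustained for at least 45 days;
#' * `switch`: at least one antidepressant stopped and at least one
#'   introduced, within the switch gap window (by default 0-180 days;
#'   set `switch_gap_min_days = 60` in the configuration for the literal
#'   60-180 day window);
#' * `resumption`: the same regimen restarts outside the relapse window,
#'   or a previously used regimen restarts after discontinuation and the
#'   pair is not a relapse;
#' * `continuation_boundary`: one or more drugs dropped, nothing added;
#' * `none`: anything else (including relapse restarts of the same
#'   regimen, which are reported as relapse events, not transitions).
#'
#' @param prev_seq,next_seq Single rows of a sequence table, consecutive
#'   for one patient.
#' @param cfg A [study_config()].
#' @param previously_used Character vector of regimen keys used by this
#'   patient before `prev_seq` (for resumption detection).
#' @return One of `"combination"`, `"switch"`, `"resumption"`,
#'   `"continuation_boundary"`, `"none"`.
#' @export
classify_transition <- function(prev_seq, next_seq, cfg = study_config(),
                                previously_used = character()) {
  gap <- as.integer(next_seq$start - prev_seq$end)
  if (gap < 0L) {
    stop("overlapping sequences passed to classify_transition ",
         "(sequence construction bug)")
  }
  prev_set <- split_regimen(prev_seq$regimen)
  next_set <- split_regimen(next_seq$regimen)
  added <- setdiff(next_set, prev_set)
  removed <- setdiff(prev_set, next_set)
  same <- length(added) == 0L && length(removed) == 0L
  rw <- cfg$relapse_window_days
  prev_responded <- prev_seq$duration_days >= cfg$response_min_days
  is_relapse_pair <- prev_responded && gap >= rw[1] && gap <= rw[2]

  if (length(removed) == 0L && length(added) > 0L &&
      next_seq$duration_days >= cfg$combination_min_days) {
    return("combination")
  }
  if (length(added) > 0L && length(removed) > 0L &&
      gap >= cfg$switch_gap_min_days && gap <= cfg$switch_gap_max_days) {
    return("switch")
  }
  if (same && !is_relapse_pair) return("resumption")
  if (!same && next_seq$regimen %in% previously_used && !is_relapse_pair) {
    return("resumption")
  }
  if (length(removed) > 0L && length(added) == 0L) {
    return("continuation_boundary")
  }
  "none"
}

# All per-patient rule outputs in one pass; the exported detect_* /
# count_lines / classify_patient functions are views onto this.
patient_pathway_state <- function(seqs, augmentations = NULL, doses = NULL,
                                  dict = NULL, cfg = study_config()) {
  n <- nrow(seqs)
  stopifnot(n > 0L)
  response <- detect_response(seqs, cfg)
  remission <- detect_remission(seqs, cfg)
  remission_clause <- attr(remission, "clause")
  relapse <- detect_relapse(seqs, cfg)

  transition <- rep(NA_character_, n)
  gap <- rep(NA_integer_, n)
  if (n > 1L) {
    for (j in 2:n) {
      gap[j] <- as.integer(seqs$start[j] - seqs$end[j - 1L])
      used_before <- unique(seqs$regimen[seq_len(j - 1L)])
      transition[j] <- classify_transition(seqs[j - 1L, ], seqs[j, ], cfg,
                                           previously_used = used_before)
    }
  }

  augmented <- logical(n)
  if (!is.null(augmentations) && nrow(augmentations) > 0L) {
    augmented[seqs$sequence_ordinal %in% augmentations$sequence_ordinal] <- TRUE
  }

  # failure: no response, or followed (within the episode) by a switch or
  # combination, or augmented
  followed_by_change <- c(
    transition[-1] %in% c("switch", "combination") &
      gap[-1] <= cfg$episode_gap_days,
    FALSE
  )
  failure <- !response | followed_by_change | augmented

  # episode boundaries: treatment-free gap beyond the episode gap, or a
  # remission on the previous sequence
  episode <- integer(n)
  episode[1] <- 1L
  if (n > 1L) {
    for (j in 2:n) {
      new_ep <- gap[j] > cfg$episode_gap_days || isTRUE(remission[j - 1L])
      episode[j] <- episode[j - 1L] + as.integer(new_ep)
    }
  }

  # line initiations: episode start, or a switch/combination transition
  initiation <- episode != c(0L, episode[-n]) |
    transition %in% c("switch", "combination")
  initiation[1] <- TRUE

  # adequacy: duration, plus dose where both a recorded dose and a
  # dictionary minimum exist
  adequate <- seqs$duration_days >= cfg$adequate_line_min_days
  if (!is.null(doses) && !is.null(dict) && nrow(doses) > 0L) {
    mins <- dict$drugs$min_daily_dose[match(doses$ingredient,
                                            dict$drugs$ingredient)]
    underdosed <- !is.na(doses$max_dose) & !is.na(mins) &
      doses$max_dose < mins
    bad_seq <- unique(doses$sequence_ordinal[underdosed])
    adequate[seqs$sequence_ordinal %in% bad_seq] <- FALSE
  }

  lines_by_episode <- vapply(split(seq_len(n), episode), function(idx) {
    length(unique(seqs$regimen[idx][initiation[idx]]))
  }, integer(1))

  # resistance counts failed *lines*: only sequences that initiate a line
  # are eligible, so a short-lived drug addition that never qualified as a
  # combination cannot manufacture a failed line
  trd_by_episode <- vapply(split(seq_len(n), episode), function(idx) {
    length(unique(seqs$regimen[idx][failure[idx] & adequate[idx] &
                                      initiation[idx]])) >= 2L
  }, logical(1))

  list(response = response, remission = as.logical(remission),
       remission_clause = remission_clause, relapse = relapse,
       transition = transition, gap = gap, augmented = augmented,
       failure = failure, episode = episode, initiation = initiation,
       adequate = adequate, lines_by_episode = lines_by_episode,
       lines = max(lines_by_episode), trd = any(trd_by_episode))
}

#' Detect treatment failure per sequence
#'
#' A sequence is a failed line when it produced no response, or it was
#' followed within the episode by a switch or combination, or an
#' augmentation agent was attached to it.
#'
#' @inheritParams detect_response
#' @param augmentations Augmentation attachments for this patient
#'   ([attach_augmentations()]), or NULL.
#' @return Logical vector per sequence.
#' @export
detect_treatment_failure <- function(seqs, augmentations = NULL,
                                     cfg = study_config()) {
  patient_pathway_state(seqs, augmentations, cfg = cfg)$failure
}

#' Count lines of therapy
#'
#' A line is a distinct regimen initiated by the first sequence of an
#' episode, a switch, or a combination; resumptions of a previously tried
#' regimen do not start a new line. Returns the largest line count reached
#' within any single episode.
#'
#' @inheritParams detect_treatment_failure
#' @return Integer, at least 1.
#' @export
count_lines <- function(seqs, augmentations = NULL, cfg = study_config()) {
  patient_pathway_state(seqs, augmentations, cfg = cfg)$lines
}

#' Classify one patient as MDD or TRD
#'
#' Treatment-resistant depression requires, within a single depressive
#' episode, at least two failed lines with differing regimens, each of
#' adequate duration (and adequate dose where both a recorded dose and a
#' dictionary minimum effective dose exist). An episode is closed by a
#' remission or by a treatment-free gap exceeding the episode gap
#' (strictly greater than 180 days, so a relapse at exactly the upper
#' relapse bound stays within its episode).
#'
#' @inheritParams detect_treatment_failure
#' @param dict A [code_dictionary][load_code_dictionary] supplying minimum
#'   effective doses, or NULL to skip dose adequacy.
#' @return A list with `classification` (one-row data frame: `patient_id`,
#'   `group`, `lines_of_therapy`, `failure_count`, `trd_2_lines`,
#'   `trd_3plus_lines`, `trd_4plus_lines`, `n_responses`, `n_relapses`,
#'   `n_resumptions`, `remission_flag`) and `events` (one row per pathway
#'   event with anchor dates and a rule trace).
#' @export
classify_patient <- function(seqs, augmentations = NULL, dict = NULL,
                             cfg = study_config()) {
  stopifnot(nrow(seqs) > 0L, length(unique(seqs$patient_id)) == 1L)
  pid <- seqs$patient_id[1]
  st <- patient_pathway_state(seqs, augmentations,
                              doses = attr(seqs, "doses"), dict = dict,
                              cfg = cfg)
  n <- nrow(seqs)
  ev <- list()
  add_event <- function(type, ordinal, date, trace) {
    ev[[length(ev) + 1L]] <<- data.frame(
      patient_id = pid, event_type = type, sequence_ordinal = ordinal,
      event_date = pmin(date, cfg$study_end), rule_trace = trace,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n)) {
    if (st$response[i]) {
      add_event("response", i, seqs$start[i] + cfg$response_min_days,
                sprintf("regimen %s sustained %d d (>= %d)",
                        seqs$regimen[i], seqs$duration_days[i],
                        cfg$response_min_days))
    }
    if (st$remission[i]) {
      if (identical(st$remission_clause[i], "duration")) {
        add_event("remission", i, seqs$start[i] + cfg$remission_response_days,
                  sprintf("response sustained %d d (>= %d)",
                          seqs$duration_days[i], cfg$remission_response_days))
      } else {
        add_event("remission", i, seqs$end[i],
                  sprintf("sequence of %d d (>= %d) with no antidepressant in the %d d after its end",
                          seqs$duration_days[i], cfg$response_min_days,
                          cfg$remission_gap_days))
      }
    }
    if (st$relapse[i]) {
      add_event("relapse", i, seqs$start[i],
                sprintf("new sequence %d d after end of responding sequence %d (window %d-%d)",
                        st$gap[i], i - 1L, cfg$relapse_window_days[1],
                        cfg$relapse_window_days[2]))
    }
    if (!is.na(st$transition[i]) &&
        st$transition[i] %in% c("switch", "combination", "resumption")) {
      add_event(st$transition[i], i, seqs$start[i],
                sprintf("%s -> %s after %d d gap", seqs$regimen[i - 1L],
                        seqs$regimen[i], st$gap[i]))
    }
    if (st$augmented[i]) {
      rows <- augmentations[augmentations$sequence_ordinal ==
                              seqs$sequence_ordinal[i], , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        add_event("augmentation", i, rows$overlap_start[k],
                  sprintf("%s (%s) overlapping %d d (>= %d)", rows$agent[k],
                          rows$agent_class[k], rows$overlap_days[k],
                          cfg$augmentation_min_days))
      }
    }
    if (st$failure[i]) {
      clauses <- c(
        if (!st$response[i]) "no response",
        if (i < n && !is.na(st$transition[i + 1L]) &&
            st$transition[i + 1L] %in% c("switch", "combination") &&
            st$gap[i + 1L] <= cfg$episode_gap_days)
          paste("followed by", st$transition[i + 1L]),
        if (st$augmented[i]) "augmented"
      )
      add_event("treatment_failure", i, seqs$end[i],
                paste(clauses, collapse = "; "))
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else data.frame(
    patient_id = character(), event_type = character(),
    sequence_ordinal = integer(), event_date = as.Date(character()),
    rule_trace = character(), stringsAsFactors = FALSE
  )
  classification <- data.frame(
    patient_id = pid,
    group = if (st$trd) "TRD" else "MDD",
    lines_of_therapy = st$lines,
    failure_count = sum(st$failure),
    trd_2_lines = st$trd & st$lines == 2L,
    trd_3plus_lines = st$trd & st$lines >= 3L,
    trd_4plus_lines = st$trd & st$lines >= 4L,
    n_responses = sum(st$response),
    n_relapses = sum(st$relapse),
    n_resumptions = sum(st$transition == "resumption", na.rm = TRUE),
    n_switches = sum(st$transition == "switch", na.rm = TRUE),
    n_combinations = sum(st$transition == "combination", na.rm = TRUE),
    n_augmentations = sum(st$augmented),
    remission_flag = any(st$remission),
    stringsAsFactors = FALSE
  )
  list(classification = classification, events = events)
}

#' Run the full pathway derivation over a cohort
#'
#' Builds antidepressant and augmentation coverage, derives treatment
#' sequences, attaches augmentations, classifies every eligible patient's
#' pathway events, and assembles the patient-level MDD/TRD classification
#' with the mental-health-services contact flag.
#'
#' @param prescriptions All prescription records ([read_prescriptions()]).
#' @param events All clinical events, or NULL.
#' @param contacts Secondary-care contacts ([read_contacts()]), or NULL.
#' @param cohort Cohort table from [build_cohort()].
#' @param dict A code dictionary.
#' @param cfg A [study_config()].
#' @return A list with `sequences`, `augmentations`, `events` (pathway
#'   events) and `classifications`.
#' @export
derive_pathways <- function(prescriptions, events = NULL, contacts = NULL,
                            cohort, dict = default_code_dictionary(),
                            cfg = study_config()) {
  eligible <- cohort$patient_id[cohort$eligible]
  rx <- prescriptions[prescriptions$patient_id %in% eligible, , drop = FALSE]
  cov <- expand_and_merge_coverage(rx, cfg, role = "antidepressant")
  aug_cov <- expand_and_merge_coverage(rx, cfg, role = "augmentation_agent")
  seqs <- derive_sequences(cov, cfg)
  doses <- attr(seqs, "doses")
  augs <- attach_augmentations(seqs, aug_cov, cfg)

  mhs_ids <- character()
  if (!is.null(events) && nrow(events) > 0L) {
    mhs_ids <- c(mhs_ids, events$patient_id[events$category %in%
                                              c("mhs_referral", "mhs_contact")])
  }
  if (!is.null(contacts) && nrow(contacts) > 0L) {
    mhs_ids <- c(mhs_ids, contacts$patient_id)
  }
  mhs_ids <- unique(mhs_ids)

  by_patient <- split(seq_len(nrow(seqs)), seqs$patient_id)
  dose_by <- split(seq_len(nrow(doses)), doses$patient_id)
  aug_by <- split(seq_len(nrow(augs)), augs$patient_id)
  cls <- list(); evs <- list()
  for (pid in names(by_patient)) {
    pseq <- seqs[by_patient[[pid]], , drop = FALSE]
    attr(pseq, "doses") <- doses[dose_by[[pid]] %||% integer(), ,
                                 drop = FALSE]
    paug <- augs[aug_by[[pid]] %||% integer(), , drop = FALSE]
    res <- classify_patient(pseq, paug, dict = dict, cfg = cfg)
    cls[[pid]] <- res$classification
    evs[[pid]] <- res$events
  }
  classifications <- do.call(rbind, cls)
  rownames(classifications) <- NULL
  classifications$mhs_contact <- classifications$patient_id %in% mhs_ids
  pathway_events <- do.call(rbind, evs)
  rownames(pathway_events) <- NULL
  list(sequences = seqs, augmentations = augs, events = pathway_events,
       classifications = classifications)
}
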