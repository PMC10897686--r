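# Label-first synthetic cohort generator.
#
# Trajectories are written top-down from intended labels: each patient is
# assigned a group and a path template whose classifier outcome is known
# by construction, then the template is rendered into ~30-day scripts with
# adherence gaps. This guarantees unambiguous ground truth for rule
# testing, at the cost of calendar realism (dates are uniform over the
# window, no weekends or holidays).

#' Generator configuration
#'
#' Defaults emulate the structure of the study population: 8% of eligible
#' patients destined for treatment resistance; four drugs (citalopram,
#' sertraline, fluoxetine, mirtazapine) carrying ~83% of prescribing mass;
#' ~30-day scripts with mostly short adherence gaps; response and relapse
#' probabilities per group; comorbidity, suicidality and secondary
#' mental-health contact rates higher in the resistant group; a mean
#' contact delay of about 40 months after the first depression code.
#'
#' @param n_patients Number of patients to simulate.
#' @param trd_proportion Probability an eligible patient is destined for
#'   treatment resistance.
#' @param response_prob Named (MDD, TRD): probability the trajectory
#'   includes a treatment response. For resistant patients this applies to
#'   the line following their failed lines, so it also sets their
#'   remission rate.
#' @param relapse_prob Named (MDD, TRD): probability of a relapse given a
#'   response.
#' @param fail_pre_prob Probability a responding non-resistant patient's
#'   trajectory is preceded by one failed line ended by a switch.
#' @param trd_failed_lines_probs Probabilities of 2, 3 or 4 failed lines
#'   for resistant patients.
#' @param drug_weights Named sampling weights over antidepressant
#'   ingredients (normalized internally).
#' @param gap_mixture Adherence gap distribution between scripts:
#'   `p_short` chance of a gap uniform on `short`, else uniform on `long`
#'   (all below the coverage-merge tolerance, so gaps exercise merging
#'   without breaking sequences).
#' @param dose_increase_prob Chance a line doubles its dose halfway.
#' @param missing_dose_prob Chance a script has no recorded dose.
#' @param augmentation_prob Named (MDD, TRD): chance of an augmentation
#'   agent attached to a line (for non-resistant patients only applied to
#'   single-regimen trajectories, so augmentation never manufactures
#'   resistance).
#' @param comorbidity_prev List of named (MDD, TRD) prevalences per
#'   comorbidity.
#' @param suicidality_prob Named (MDD, TRD): chance of suicidality codes.
#' @param mhs_contact_prob Named (MDD, TRD): chance of secondary
#'   mental-health contact.
#' @param mhs_delay_months_mean,mhs_delay_months_sd Gamma-distributed
#'   delay from first depression code to first contact, in months.
#' @param dep_code_after_prob Chance the depression code is recorded
#'   shortly after the first prescription rather than before it.
#' @param ineligible_fraction Fraction of generated patients violating an
#'   eligibility rule (minors, exclusion diagnoses, missing depression
#'   code, prescriptions only before the study window), to exercise the
#'   cohort builder.
#' @param rng_seed Mandatory seed; identical configurations and seeds
#'   produce byte-identical output files.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000L,
                             trd_proportion = 0.08,
                             response_prob = c(MDD = 0.30, TRD = 0.13),
                             relapse_prob = c(MDD = 0.30, TRD = 0.50),
                             fail_pre_prob = 0.30,
                             trd_failed_lines_probs = c(`2` = 0.67,
                                                        `3` = 0.24,
                                                        `4` = 0.09),
                             drug_weights = c(citalopram = 0.35,
                                              sertraline = 0.18,
                                              fluoxetine = 0.16,
                                              mirtazapine = 0.14,
                                              venlafaxine = 0.06,
                                              amitriptyline = 0.05,
                                              paroxetine = 0.03,
                                              duloxetine = 0.03),
                             gap_mixture = list(p_short = 0.85,
                                                short = c(0L, 10L),
                                                long = c(25L, 55L)),
                             dose_increase_prob = 0.2,
                             missing_dose_prob = 0.05,
                             augmentation_prob = c(MDD = 0.04, TRD = 0.35),
                             comorbidity_prev = list(
                               anxiety = c(MDD = 0.27, TRD = 0.48),
                               asthma = c(MDD = 0.15, TRD = 0.18),
                               alcohol_substance = c(MDD = 0.08, TRD = 0.14),
                               diabetes = c(MDD = 0.09, TRD = 0.10)
                             ),
                             suicidality_prob = c(MDD = 0.06, TRD = 0.12),
                             mhs_contact_prob = c(MDD = 0.21, TRD = 0.54),
                             mhs_delay_months_mean = 40,
                             mhs_delay_months_sd = 32,
                             dep_code_after_prob = 0.10,
                             ineligible_fraction = 0.05,
                             rng_seed = 42L) {
  gc <- list(
    n_patients = as.integer(n_patients),
    trd_proportion = trd_proportion,
    response_prob = response_prob,
    relapse_prob = relapse_prob,
    fail_pre_prob = fail_pre_prob,
    trd_failed_lines_probs = trd_failed_lines_probs /
      sum(trd_failed_lines_probs),
    drug_weights = drug_weights / sum(drug_weights),
    gap_mixture = gap_mixture,
    dose_increase_prob = dose_increase_prob,
    missing_dose_prob = missing_dose_prob,
    augmentation_prob = augmentation_prob,
    comorbidity_prev = comorbidity_prev,
    suicidality_prob = suicidality_prob,
    mhs_contact_prob = mhs_contact_prob,
    mhs_delay_months_mean = mhs_delay_months_mean,
    mhs_delay_months_sd = mhs_delay_months_sd,
    dep_code_after_prob = dep_code_after_prob,
    ineligible_fraction = ineligible_fraction,
    rng_seed = as.integer(rng_seed)
  )
  validate_generator_config(gc)
  structure(gc, class = "generator_config")
}

validate_generator_config <- function(gc) {
  probs <- c(gc$trd_proportion, gc$response_prob, gc$relapse_prob,
             gc$fail_pre_prob, gc$dose_increase_prob, gc$missing_dose_prob,
             gc$augmentation_prob, unlist(gc$comorbidity_prev),
             gc$suicidality_prob, gc$mhs_contact_prob,
             gc$dep_code_after_prob, gc$ineligible_fraction,
             gc$gap_mixture$p_short)
  if (any(probs < 0 | probs > 1)) stop("infeasible config: probability outside [0, 1]")
  if (gc$n_patients < 1L) stop("infeasible config: n_patients < 1")
  if (any(gc$drug_weights <= 0)) stop("infeasible config: nonpositive drug weight")
  if (length(gc$drug_weights) < 5L) {
    stop("infeasible config: need at least 5 antidepressants for 4 failed lines plus a final line")
  }
  if (is.na(gc$rng_seed)) stop("infeasible config: rng_seed is mandatory")
  if (gc$mhs_delay_months_mean <= 0 || gc$mhs_delay_months_sd <= 0) {
    stop("infeasible config: contact delay parameters must be positive")
  }
  stopifnot(all(c("MDD", "TRD") %in% names(gc$response_prob)),
            all(c("MDD", "TRD") %in% names(gc$relapse_prob)))
  invisible(gc)
}

sample_gap <- function(gm) {
  if (stats::runif(1) < gm$p_short) {
    sample(gm$short[1]:gm$short[2], 1L)
  } else {
    sample(gm$long[1]:gm$long[2], 1L)
  }
}

# scripts for one line: day offsets (relative to line start) such that
# 30-day supplies with gaps below the merge tolerance cover exactly
# [0, duration)
line_script_days <- function(duration, gm) {
  stopifnot(duration >= 30L)
  ts <- 0L; t <- 0L
  repeat {
    nxt <- t + 30L + sample_gap(gm)
    if (nxt > duration - 30L) break
    ts <- c(ts, nxt); t <- nxt
  }
  if (t < duration - 30L) ts <- c(ts, duration - 30L)
  ts
}

# render one line into script rows (day offsets from treatment start)
render_line <- function(drug, start_day, duration, base_dose, gc) {
  days <- start_day + line_script_days(duration, gc$gap_mixture)
  dose <- rep(base_dose, length(days))
  if (stats::runif(1) < gc$dose_increase_prob && length(days) > 1L) {
    half <- days >= start_day + duration %/% 2L
    dose[half] <- base_dose * 2
  }
  dose[stats::runif(length(days)) < gc$missing_dose_prob] <- NA_real_
  data.frame(day = days, drug = drug, daily_dose = dose,
             supply_days = 30L, stringsAsFactors = FALSE)
}

runi <- function(lo, hi) sample(lo:hi, 1L)

# Build one patient's trajectory (in day offsets) from its intended
# labels. Returns scripts, augmentation scripts, and truth fields.
build_trajectory <- function(group, gc, doses_by_drug) {
  drugs <- names(gc$drug_weights)
  pick <- function(n, exclude = character()) {
    pool <- setdiff(drugs, exclude)
    sample(pool, n, prob = gc$drug_weights[pool])
  }
  scripts <- list(); aug <- NULL
  lines <- list()  # bookkeeping for augmentation placement
  add_line <- function(drug, start, duration) {
    scripts[[length(scripts) + 1L]] <<- render_line(
      drug, start, duration, doses_by_drug[[drug]], gc)
    lines[[length(lines) + 1L]] <<- list(drug = drug, start = start,
                                         duration = duration)
  }

  has_response <- stats::runif(1) < gc$response_prob[[group]]
  has_relapse <- has_response && stats::runif(1) < gc$relapse_prob[[group]]
  true_lines <- 1L
  template <- NULL
  t <- 0L
  single_regimen <- FALSE

  if (group == "TRD") {
    k <- as.integer(sample(names(gc$trd_failed_lines_probs), 1L,
                           prob = gc$trd_failed_lines_probs))
    ds <- pick(k + 1L)
    for (i in seq_len(k)) {
      dur <- runi(45L, 85L)
      add_line(ds[i], t, dur)
      t <- t + dur
      if (i < k || has_response) t <- t + runi(0L, 50L)  # switch gap
    }
    if (has_response) {
      dur <- runi(90L, 175L)
      add_line(ds[k + 1L], t, dur)
      t <- t + dur
      if (has_relapse) {
        t <- t + runi(61L, 179L)
        dur <- runi(45L, 89L)
        add_line(ds[k + 1L], t, dur)
        t <- t + dur
      }
    }
    true_lines <- k + as.integer(has_response)
    template <- paste0("trd_", k, "fail",
                       if (has_response) "_resp" else "",
                       if (has_relapse) "_rel" else "")
  } else if (has_response) {
    fail_pre <- stats::runif(1) < gc$fail_pre_prob
    d1 <- pick(1L)
    if (fail_pre) {
      dur <- runi(45L, 85L)
      add_line(d1, t, dur)
      t <- t + dur + runi(0L, 50L)
      d2 <- pick(1L, exclude = d1)
    } else {
      d2 <- d1
    }
    if (has_relapse) {
      dur <- runi(90L, 175L)
      add_line(d2, t, dur)
      t <- t + dur + runi(61L, 179L)
      dur2 <- runi(45L, 89L)
      add_line(d2, t, dur2)
      t <- t + dur2
      template <- "respond_relapse"
    } else if (stats::runif(1) < 0.5) {
      dur <- runi(181L, 420L)
      add_line(d2, t, dur)
      t <- t + dur
      template <- "respond_remit_long"
    } else {
      dur <- runi(90L, 175L)
      add_line(d2, t, dur)
      t <- t + dur
      template <- "respond_remit_gap"
    }
    true_lines <- 1L + as.integer(fail_pre)
  } else {
    # chronic non-responder: one regimen, resumed after gaps
    d1 <- pick(1L)
    single_regimen <- TRUE
    k_res <- runi(0L, 3L)
    dur <- runi(45L, 89L)
    add_line(d1, t, dur)
    t <- t + dur
    for (i in seq_len(k_res)) {
      t <- t + runi(61L, 179L)
      dur <- runi(45L, 89L)
      add_line(d1, t, dur)
      t <- t + dur
    }
    true_lines <- 1L
    template <- paste0("chronic_", k_res, "res")
  }

  # augmentation: attach an agent to one line; for non-resistant patients
  # only on single-regimen trajectories so resistance is never created
  aug_ok <- group == "TRD" || single_regimen
  if (aug_ok && stats::runif(1) < gc$augmentation_prob[[group]]) {
    li <- lines[[sample(length(lines), 1L)]]
    aug <- data.frame(day = c(li$start, li$start + 30L),
                      agent = sample(c("lithium", "quetiapine",
                                       "olanzapine", "levothyroxine",
                                       "liothyronine", "lamotrigine"), 1L),
                      supply_days = 30L, stringsAsFactors = FALSE)
  }

  list(scripts = do.call(rbind, scripts), aug = aug, total_days = t,
       true_lines = true_lines, template = template,
       has_response = has_response, has_relapse = has_relapse)
}

#' Generate a synthetic primary-care cohort with ground-truth labels
#'
#' Simulates per-patient prescription streams, coded clinical events,
#' secondary-care contacts and demographics, together with a truth table
#' recording each patient's intended group (MDD or TRD), line count and
#' trajectory template. Deterministic given the configuration seed.
#'
#' @param gc A [generator_config()].
#' @param dict Code dictionary used to emit drug and clinical codes.
#' @param cfg A [study_config()].
#' @param out_dir If non-NULL, the five CSV files (`prescriptions.csv`,
#'   `events.csv`, `contacts.csv`, `demographics.csv`, `truth.csv`) are
#'   written there.
#' @return A list of data frames `prescriptions` (raw reader format),
#'   `events`, `contacts`, `demographics`, `truth`, plus `paths` when
#'   files were written.
#' @export
generate_cohort <- function(gc = generator_config(),
                            dict = default_code_dictionary(),
                            cfg = study_config(), out_dir = NULL) {
  validate_generator_config(gc)
  set.seed(gc$rng_seed)
  window_days <- as.integer(cfg$study_end - cfg$study_start)
  drugs <- names(gc$drug_weights)
  doses_by_drug <- as.list(dict$drugs$min_daily_dose[
    match(drugs, dict$drugs$ingredient)])
  names(doses_by_drug) <- drugs
  if (anyNA(unlist(doses_by_drug))) {
    stop("generator drug_weights name ingredients absent from the dictionary")
  }
  dep_codes <- dict$clinical$code[dict$clinical$category == "depression"]
  exc_codes <- dict$clinical$code[dict$clinical$category == "exclusion"]
  sui_codes <- dict$clinical$code[dict$clinical$category == "suicidality"]
  ref_code <- dict$clinical$code[dict$clinical$category == "mhs_referral"][1]
  com_codes <- c(anxiety = "COM01", asthma = "COM02",
                 alcohol_substance = "COM03", diabetes = "COM04")

  n <- gc$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  rx <- list(); ev <- list(); ct <- list(); dm <- list(); tr <- list()
  add_ev <- function(pid, code, date) {
    ev[[length(ev) + 1L]] <<- data.frame(
      patient_id = pid, code = code, code_system = "read_v2",
      event_date = date, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    pid <- ids[i]
    ineligible <- stats::runif(1) < gc$ineligible_fraction
    inel_type <- if (ineligible) {
      sample(c("under_18", "exclusion_code", "no_depression_code",
               "no_antidepressant_in_window"), 1L)
    } else NA_character_
    group <- if (stats::runif(1) < gc$trd_proportion) "TRD" else "MDD"
    traj <- build_trajectory(group, gc, doses_by_drug)

    if (identical(inel_type, "no_antidepressant_in_window")) {
      index <- cfg$study_start - runi(400L, 700L)  # all scripts pre-window
      traj$scripts <- traj$scripts[traj$scripts$day <= 300L, , drop = FALSE]
      if (nrow(traj$scripts) == 0L) {
        traj$scripts <- data.frame(day = 0L, drug = drugs[1],
                                   daily_dose = doses_by_drug[[1]],
                                   supply_days = 30L)
      }
      traj$aug <- NULL
    } else {
      slack <- window_days - traj$total_days - 61L
      stopifnot(slack >= 0L)
      index <- cfg$study_start + runi(0L, slack)
    }

    s <- traj$scripts
    rx[[length(rx) + 1L]] <- data.frame(
      patient_id = pid,
      drug_code = dict_code_for_ingredient(dict, s$drug),
      issue_date = index + s$day,
      daily_dose = s$daily_dose,
      supply_days = s$supply_days,
      stringsAsFactors = FALSE
    )
    if (!is.null(traj$aug)) {
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = pid,
        drug_code = dict_code_for_ingredient(dict, traj$aug$agent),
        issue_date = index + traj$aug$day,
        daily_dose = NA_real_,
        supply_days = traj$aug$supply_days,
        stringsAsFactors = FALSE
      )
    }

    # depression code (sometimes recorded after the first prescription)
    dep_date <- as.Date(NA)
    if (!identical(inel_type, "no_depression_code")) {
      dep_date <- if (stats::runif(1) < gc$dep_code_after_prob &&
                      !identical(inel_type, "no_antidepressant_in_window")) {
        index + runi(1L, 60L)
      } else {
        max(index - runi(0L, 1500L), as.Date("2005-01-01"))
      }
      add_ev(pid, sample(dep_codes, 1L), dep_date)
    }
    if (identical(inel_type, "exclusion_code")) {
      add_ev(pid, sample(exc_codes, 1L),
             as.Date("2012-01-01") + runi(0L, 3000L))
    }
    for (com in names(gc$comorbidity_prev)) {
      if (stats::runif(1) < gc$comorbidity_prev[[com]][[group]]) {
        add_ev(pid, com_codes[[com]], cfg$study_start + runi(0L, window_days))
      }
    }
    if (stats::runif(1) < gc$suicidality_prob[[group]]) {
      for (k in seq_len(runi(1L, 3L))) {
        add_ev(pid, sample(sui_codes, 1L),
               cfg$study_start + runi(0L, window_days))
      }
    }
    has_contact <- !is.na(dep_date) &&
      stats::runif(1) < gc$mhs_contact_prob[[group]]
    if (has_contact) {
      shape <- (gc$mhs_delay_months_mean / gc$mhs_delay_months_sd)^2
      scale <- gc$mhs_delay_months_mean / shape
      delay <- round(stats::rgamma(1, shape = shape, scale = scale) *
                       cfg$month_length_days)
      cdate <- min(dep_date + delay, cfg$study_end)
      # contact is always recorded in the service's own table; a GP
      # referral code accompanies it only sometimes (contacts can arrive
      # via A&E and other non-GP routes)
      if (stats::runif(1) < 0.6) add_ev(pid, ref_code, cdate)
      ct[[length(ct) + 1L]] <- data.frame(
        patient_id = pid, contact_date = cdate,
        setting = sample(c("outpatient", "inpatient", "a_and_e", "crisis",
                           "community", "liaison", "home"), 1L),
        stringsAsFactors = FALSE)
    }

    dob_days <- if (identical(inel_type, "under_18")) {
      runi(5200L, 6500L)        # 14-17 years old at index
    } else {
      runi(6600L, 32000L)       # 18-87 years old at index
    }
    dm[[length(dm) + 1L]] <- data.frame(
      patient_id = pid, date_of_birth = index - dob_days,
      gender = sample(c("F", "M"), 1L, prob = c(2, 1)),
      stringsAsFactors = FALSE)

    tr[[length(tr) + 1L]] <- data.frame(
      patient_id = pid,
      eligible = !ineligible,
      ineligible_type = inel_type,
      true_group = group,
      true_lines = traj$true_lines,
      template = traj$template,
      n_scripts = if (identical(inel_type, "no_antidepressant_in_window"))
        0L else nrow(traj$scripts),
      has_response = traj$has_response,
      has_relapse = traj$has_relapse,
      mhs_contact = has_contact,
      stringsAsFactors = FALSE)
  }

  out <- list(
    prescriptions = do.call(rbind, rx),
    events = do.call(rbind, ev),
    contacts = if (length(ct)) do.call(rbind, ct) else
      data.frame(patient_id = character(),
                 contact_date = as.Date(character()),
                 setting = character(), stringsAsFactors = FALSE),
    demographics = do.call(rbind, dm),
    truth = do.call(rbind, tr)
  )
  out$prescriptions <- out$prescriptions[
    order(out$prescriptions$patient_id, out$prescriptions$issue_date,
          out$prescriptions$drug_code), , drop = FALSE]
  rownames(out$prescriptions) <- NULL
  out$events <- out$events[order(out$events$patient_id,
                                 out$events$event_date, out$events$code), ,
                           drop = FALSE]
  rownames(out$events) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      prescriptions = file.path(out_dir, "prescriptions.csv"),
      events = file.path(out_dir, "events.csv"),
      contacts = file.path(out_dir, "contacts.csv"),
      demographics = file.path(out_dir, "demographics.csv"),
      truth = file.path(out_dir, "truth.csv")
    )
    for (nm in names(paths)) write_records(out[[nm]], paths[[nm]])
    out$paths <- paths
  }
  out
}

#' Compare pipeline estimates against generator parameters
#'
#' Runs parameter recovery on a generated cohort: the estimated proportion
#' of treatment-resistant patients, per-group response rates, per-group
#' relapse rates among responders, and mean scripts per patient are
#' compared with the configured generator values, reporting the absolute
#' error, the binomial/normal standard error at the configured value, and
#' whether the estimate falls within three standard errors. Also reports
#' classifier-versus-truth agreement on group labels and line counts.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param classifications Classifications from [derive_pathways()].
#' @param metrics Patient metrics from [compute_patient_metrics()].
#' @param gc The [generator_config()] that produced the cohort.
#' @return A data frame (one row per recovered quantity) with attributes
#'   `group_agreement` and `lines_agreement`.
#' @export
recover_parameters <- function(truth, classifications, metrics, gc) {
  elig <- truth[truth$eligible, , drop = FALSE]
  if (!setequal(elig$patient_id, classifications$patient_id)) {
    stop("mismatched patient universes between truth and classifications")
  }
  cls <- classifications[match(elig$patient_id,
                               classifications$patient_id), , drop = FALSE]
  met <- metrics[match(elig$patient_id, metrics$patient_id), , drop = FALSE]

  rows <- list()
  add <- function(quantity, configured, estimated, n_eff) {
    se <- sqrt(configured * (1 - configured) / n_eff)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, configured = configured, estimated = estimated,
      abs_error = abs(estimated - configured), n = n_eff, se = se,
      within_3se = abs(estimated - configured) <= 3 * se,
      stringsAsFactors = FALSE)
  }
  add("trd_proportion", gc$trd_proportion, mean(cls$group == "TRD"),
      nrow(cls))
  for (g in c("MDD", "TRD")) {
    in_g <- cls$group == g
    add(paste0("response_rate_", g), gc$response_prob[[g]],
        mean(cls$n_responses[in_g] >= 1L), sum(in_g))
    resp <- in_g & cls$n_responses >= 1L
    if (sum(resp) > 0L) {
      add(paste0("relapse_rate_", g), gc$relapse_prob[[g]],
          mean(cls$n_relapses[resp] >= 1L), sum(resp))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "group_agreement") <- mean(cls$group == elig$true_group)
  attr(out, "lines_agreement") <-
    mean(cls$lines_of_therapy == elig$true_lines)
  attr(out, "script_count_agreement") <-
    mean(met$n_prescriptions == elig$n_scripts)
  attr(out, "mean_scripts_truth") <- mean(elig$n_scripts)
  attr(out, "mean_scripts_estimated") <- mean(met$n_prescriptions)
  out
}
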