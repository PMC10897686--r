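#' Time from diagnosis to first secondary mental-health contact
#'
#' Days from the earliest depression code to the earliest of a referral
#' code or any recorded contact with secondary mental health services
#' (contacts via routes other than a GP referral count too), divided by
#' the configured month length. A contact predating the depression code
#' yields a negative duration, retained with a warning as a data-quality
#' signal.
#'
#' @param events Clinical events for one patient.
#' @param contacts Contact records for one patient (may be empty).
#' @param cfg A [study_config()].
#' @return Months (numeric), or `NA` if the patient had no contact.
#' @export
time_to_first_mhs_contact <- function(events, contacts = NULL,
                                      cfg = study_config()) {
  dep <- events$event_date[events$category == "depression"]
  if (length(dep) == 0L) stop("patient has no depression code")
  candidates <- c(
    events$event_date[events$category %in% c("mhs_referral", "mhs_contact")],
    if (!is.null(contacts) && nrow(contacts) > 0L) contacts$contact_date
  )
  if (length(candidates) == 0L) return(NA_real_)
  d <- as.integer(min(candidates) - min(dep))
  if (d < 0L) {
    warning("mental-health contact predates first depression code for patient ",
            events$patient_id[1], " (", d, " days)")
  }
  d / cfg$month_length_days
}

#' Per-patient pathway metrics
#'
#' Tallies prescriptions and pathway events per eligible patient:
#' time in study (index date to study end), duration of depression (first
#' depression code to first response, or study end if no response),
#' time to first secondary mental-health contact, script counts
#' (overall, resumption-sequence, combination-sequence, attached
#' augmentation-agent scripts), response/relapse counts, remission flag,
#' and the number of suicidality records.
#'
#' @param pathways Output of [derive_pathways()].
#' @param prescriptions All prescription records.
#' @param events All clinical events.
#' @param contacts All contact records, or NULL.
#' @param cohort Cohort table from [build_cohort()].
#' @param cfg A [study_config()].
#' @return A data frame, one row per eligible patient.
#' @export
compute_patient_metrics <- function(pathways, prescriptions, events,
                                    contacts = NULL, cohort,
                                    cfg = study_config()) {
  cls <- pathways$classifications
  seqs <- pathways$sequences
  pev <- pathways$events
  augs <- pathways$augmentations
  idx <- cohort$index_date[match(cls$patient_id, cohort$patient_id)]

  rx_in <- prescriptions[prescriptions$issue_date >= cfg$study_start &
                           prescriptions$issue_date <= cfg$study_end, ,
                         drop = FALSE]
  ad_rx <- rx_in[rx_in$drug_role == "antidepressant", , drop = FALSE]
  aug_rx <- rx_in[rx_in$drug_role == "augmentation_agent", , drop = FALSE]
  n_rx <- table(ad_rx$patient_id)

  ev_by <- split(seq_len(nrow(events)), events$patient_id)
  ct_by <- if (!is.null(contacts)) {
    split(seq_len(nrow(contacts)), contacts$patient_id)
  } else list()
  pev_by <- split(seq_len(nrow(pev)), pev$patient_id)
  seq_by <- split(seq_len(nrow(seqs)), seqs$patient_id)
  aug_by <- split(seq_len(nrow(augs)), augs$patient_id)
  adrx_by <- split(seq_len(nrow(ad_rx)), ad_rx$patient_id)
  augrx_by <- split(seq_len(nrow(aug_rx)), aug_rx$patient_id)

  out <- vector("list", nrow(cls))
  for (i in seq_len(nrow(cls))) {
    pid <- cls$patient_id[i]
    pev_i <- pev[pev_by[[pid]] %||% integer(), , drop = FALSE]
    seq_i <- seqs[seq_by[[pid]] %||% integer(), , drop = FALSE]
    ev_i <- events[ev_by[[pid]] %||% integer(), , drop = FALSE]
    ct_i <- if (!is.null(contacts)) {
      contacts[ct_by[[pid]] %||% integer(), , drop = FALSE]
    } else NULL

    dep_dates <- ev_i$event_date[ev_i$category == "depression"]
    first_dep <- if (length(dep_dates)) min(dep_dates) else as.Date(NA)
    resp_dates <- pev_i$event_date[pev_i$event_type == "response"]
    dep_end <- if (length(resp_dates)) min(resp_dates) else cfg$study_end
    duration_dep <- if (is.na(first_dep)) NA_real_ else
      as.integer(dep_end - first_dep) / cfg$month_length_days

    ttc <- if (is.na(first_dep)) NA_real_ else
      time_to_first_mhs_contact(ev_i, ct_i, cfg)

    # scripts issued during combination-initiated sequences
    comb_ord <- pev_i$sequence_ordinal[pev_i$event_type == "combination"]
    comb_windows <- seq_i[seq_i$sequence_ordinal %in% comb_ord, , drop = FALSE]
    prx <- ad_rx[adrx_by[[pid]] %||% integer(), , drop = FALSE]
    n_comb_rx <- 0L
    for (w in seq_len(nrow(comb_windows))) {
      n_comb_rx <- n_comb_rx + sum(prx$issue_date >= comb_windows$start[w] &
                                     prx$issue_date < comb_windows$end[w])
    }
    # augmentation-agent scripts inside attached augmentation windows
    aug_i <- augs[aug_by[[pid]] %||% integer(), , drop = FALSE]
    parx <- aug_rx[augrx_by[[pid]] %||% integer(), , drop = FALSE]
    n_aug_rx <- 0L
    for (w in seq_len(nrow(aug_i))) {
      n_aug_rx <- n_aug_rx + sum(parx$ingredient == aug_i$agent[w] &
                                   parx$issue_date >= aug_i$overlap_start[w] &
                                   parx$issue_date < aug_i$overlap_end[w])
    }

    out[[i]] <- data.frame(
      patient_id = pid,
      months_in_study = as.integer(cfg$study_end - idx[i]) /
        cfg$month_length_days,
      duration_of_depression_months = duration_dep,
      time_to_mhs_contact_months = ttc,
      n_prescriptions = as.integer(n_rx[pid] %||% 0L),
      n_resumptions = cls$n_resumptions[i],
      n_combination_prescriptions = n_comb_rx,
      n_augmentation_prescriptions = n_aug_rx,
      n_responses = cls$n_responses[i],
      n_relapses = cls$n_relapses[i],
      remission_flag = cls$remission_flag[i],
      suicidality_record_count = sum(ev_i$category == "suicidality"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Small-cell disclosure suppression
#'
#' Renders every integer count between 0 and 4 (more generally, strictly
#' below the configured suppression ceiling) as the string `"<5"`; counts
#' of 5 or more are rendered unchanged. Total and idempotent: applying it
#' to already-suppressed output is a no-op, and no emitted cell contains a
#' bare integer in the suppressed range.
#'
#' @param x An integer vector, or a data frame whose integer-valued
#'   columns are to be suppressed (character columns pass through, which
#'   makes the operation idempotent).
#' @param cfg A [study_config()].
#' @return A character vector, or the data frame with suppressed columns
#'   converted to character.
#' @export
suppress_small_counts <- function(x, cfg = study_config()) {
  ceiling_ <- cfg$suppression_ceiling
  suppress_vec <- function(v) {
    if (is.character(v)) return(v)
    if (any(!is.na(v) & v < 0)) stop("negative count passed to suppression")
    ifelse(is.na(v), NA_character_,
           ifelse(v < ceiling_, paste0("<", ceiling_),
                  format(v, scientific = FALSE, trim = TRUE)))
  }
  if (is.data.frame(x)) {
    for (col in names(x)) {
      v <- x[[col]]
      if (is.numeric(v) && all(is.na(v) | v == round(v))) {
        x[[col]] <- suppress_vec(v)
      }
    }
    x
  } else {
    suppress_vec(x)
  }
}

group_membership <- function(classifications) {
  list(
    Overall = rep(TRUE, nrow(classifications)),
    MDD = classifications$group == "MDD",
    TRD = classifications$group == "TRD",
    `TRD3+` = classifications$trd_3plus_lines,
    `TRD4+` = classifications$trd_4plus_lines,
    MHS = classifications$mhs_contact
  )
}

#' Group summary tables
#'
#' For each analysis group (Overall, MDD, TRD, TRD with three or more
#' lines, TRD with four or more lines, and the secondary
#' mental-health-contact subgroup, which overlaps both MDD and TRD)
#' produces descriptive summaries of each patient metric (n, mean, s.d.,
#' median, range) and outcome rates (patients with at least one response,
#' relapse, remission) as percentages of the group.
#'
#' @param metrics Output of [compute_patient_metrics()].
#' @param classifications Patient classifications from
#'   [derive_pathways()].
#' @return A list with `stats` (long-format descriptive table), `rates`
#'   (group outcome percentages with numerators) and `counts` (integer
#'   group sizes, ready for [suppress_small_counts()]).
#' @export
summarize_groups <- function(metrics, classifications) {
  m <- merge(metrics, classifications[, c("patient_id", "group",
                                          "trd_3plus_lines",
                                          "trd_4plus_lines", "mhs_contact")],
             by = "patient_id")
  groups <- group_membership(m)
  numeric_metrics <- c("months_in_study", "duration_of_depression_months",
                       "time_to_mhs_contact_months", "n_prescriptions",
                       "n_resumptions", "n_combination_prescriptions",
                       "n_augmentation_prescriptions", "n_responses",
                       "n_relapses", "suicidality_record_count")
  stats_rows <- list(); rate_rows <- list(); count_rows <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    sub <- m[sel, , drop = FALSE]
    ng <- nrow(sub)
    count_rows[[gname]] <- data.frame(group = gname, n = ng,
                                      stringsAsFactors = FALSE)
    for (metric in numeric_metrics) {
      v <- sub[[metric]]
      v <- v[!is.na(v)]
      stats_rows[[paste(gname, metric)]] <- data.frame(
        group = gname, metric = metric, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else
          if (length(v) == 1L) 0 else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    outcome_counts <- c(
      response = sum(sub$n_responses >= 1L),
      relapse = sum(sub$n_relapses >= 1L),
      remission = sum(sub$remission_flag),
      mhs_contact = sum(sub$mhs_contact)
    )
    for (oc in names(outcome_counts)) {
      rate_rows[[paste(gname, oc)]] <- data.frame(
        group = gname, outcome = oc,
        count = as.integer(outcome_counts[[oc]]),
        pct = if (ng > 0L) 100 * outcome_counts[[oc]] / ng else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
    rates = do.call(rbind, c(rate_rows, list(make.row.names = FALSE))),
    counts = do.call(rbind, c(count_rows, list(make.row.names = FALSE)))
  )
}

#' Render group summaries with disclosure control applied
#'
#' Applies small-cell suppression to every count column (group sizes,
#' per-metric n, outcome numerators) and formats means and percentages to
#' one decimal place. No cell of the result contains a bare integer in
#' the suppressed range.
#'
#' @param summary Output of [summarize_groups()].
#' @param cfg A [study_config()].
#' @return A list of character data frames (`stats`, `rates`, `counts`).
#' @export
render_summary_tables <- function(summary, cfg = study_config()) {
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 1,
                                                  format = "f"))
  stats <- summary$stats
  stats$n <- suppress_small_counts(stats$n, cfg)
  for (col in c("mean", "sd", "median", "min", "max")) {
    stats[[col]] <- fmt(stats[[col]])
  }
  rates <- summary$rates
  rates$count <- suppress_small_counts(rates$count, cfg)
  rates$pct <- fmt(rates$pct)
  counts <- summary$counts
  counts$n <- suppress_small_counts(counts$n, cfg)
  list(stats = stats, rates = rates, counts = counts)
}
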