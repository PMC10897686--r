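#' Expand prescriptions into merged drug coverage intervals
#'
#' Each script is expanded to the half-open interval
#' `[issue_date, issue_date + supply_days)`. Within one patient and
#' ingredient, intervals whose gap is at most the same-regimen tolerance
#' (60 days by default) are merged into a single coverage interval;
#' overlapping scripts extend coverage to the latest end without stacking
#' supply, so early refills do not inflate duration. Dose changes are
#' recorded in a per-interval dose trace and never split an interval.
#' Coverage is censored at the day after the study end, and scripts issued
#' outside the study window are ignored: follow-up runs from the index
#' date to the study end.
#'
#' @param scripts Prescription records (any number of patients).
#' @param cfg A [study_config()].
#' @param role Drug role to expand, `"antidepressant"` (default) or
#'   `"augmentation_agent"`.
#' @param censor Logical; censor coverage at the study end (default TRUE).
#' @return A data frame with columns `patient_id`, `ingredient`,
#'   `agent_class` (augmentation agents only), `start`, `end`, and a
#'   list-column `dose_trace` of per-script `(date, daily_dose)` frames.
#' @export
expand_and_merge_coverage <- function(scripts, cfg = study_config(),
                                      role = "antidepressant",
                                      censor = TRUE) {
  proto <- data.frame(patient_id = character(), ingredient = character(),
                      agent_class = character(),
                      start = as.Date(character()),
                      end = as.Date(character()),
                      stringsAsFactors = FALSE)
  proto$dose_trace <- list()
  x <- scripts[scripts$drug_role == role, , drop = FALSE]
  if (censor && nrow(x) > 0L) {
    x <- x[x$issue_date >= cfg$study_start & x$issue_date <= cfg$study_end, ,
           drop = FALSE]
  }
  if (nrow(x) == 0L) return(proto)
  if (!"agent_class" %in% names(x)) x$agent_class <- NA_character_

  tol <- cfg$same_regimen_gap_tolerance_days
  limit <- cfg$study_end + 1L
  x <- x[order(x$patient_id, x$ingredient, x$issue_date), , drop = FALSE]
  key <- paste(x$patient_id, x$ingredient, sep = "\r")
  groups <- split(seq_len(nrow(x)), key)

  res <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- x[groups[[g]], , drop = FALSE]
    s <- rows$issue_date
    e <- rows$issue_date + rows$supply_days
    if (censor) e <- pmin(e, limit)
    # merge pass
    starts <- s[1]; ends <- e[1]; members <- list(1L)
    k <- 1L
    for (j in seq_len(nrow(rows))[-1]) {
      if (as.integer(s[j] - ends[k]) <= tol) {
        ends[k] <- max(ends[k], e[j])
        members[[k]] <- c(members[[k]], j)
      } else {
        k <- k + 1L
        starts[k] <- s[j]; ends[k] <- e[j]; members[[k]] <- j
      }
    }
    out <- data.frame(
      patient_id = rep(rows$patient_id[1], k),
      ingredient = rep(rows$ingredient[1], k),
      agent_class = rep(rows$agent_class[1], k),
      start = as.Date(starts), end = as.Date(ends),
      stringsAsFactors = FALSE
    )
    out$dose_trace <- lapply(members, function(m) {
      data.frame(date = rows$issue_date[m], daily_dose = rows$daily_dose[m])
    })
    res[[g]] <- out
  }
  out <- do.call(rbind, res)
  out <- out[order(out$patient_id, out$start, out$ingredient), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition coverage into maximal constant-regimen treatment sequences
#'
#' A treatment sequence is a maximal period over which the set of
#' concurrently covered antidepressant ingredients (the regimen) is
#' constant. The patient's timeline is cut at every date where that set
#' changes; dose changes never cut a sequence (response requires "no
#' change other than dose"), while any regimen change or full coverage gap
#' does. Because same-ingredient gaps up to the tolerance are already
#' bridged during coverage merging, identical regimens on both sides of a
#' remaining gap are always separated by more than the tolerance.
#'
#' @param coverage Output of [expand_and_merge_coverage()].
#' @param cfg A [study_config()].
#' @return A data frame with one row per sequence: `patient_id`,
#'   `sequence_ordinal`, `regimen` (ingredients sorted, `+`-joined),
#'   `n_drugs`, `start`, `end`, `duration_days`, `dose_changes`. The
#'   attribute `"doses"` holds a per-sequence, per-ingredient table of
#'   recorded doses (`max_dose`, `n_distinct_doses`) used for adequacy
#'   checks.
#' @export
derive_sequences <- function(coverage, cfg = study_config()) {
  proto <- data.frame(patient_id = character(), sequence_ordinal = integer(),
                      regimen = character(), n_drugs = integer(),
                      start = as.Date(character()), end = as.Date(character()),
                      duration_days = integer(), dose_changes = integer(),
                      stringsAsFactors = FALSE)
  dose_proto <- data.frame(patient_id = character(),
                           sequence_ordinal = integer(),
                           ingredient = character(), max_dose = numeric(),
                           n_distinct_doses = integer(),
                           stringsAsFactors = FALSE)
  if (nrow(coverage) == 0L) {
    attr(proto, "doses") <- dose_proto
    return(proto)
  }
  by_patient <- split(seq_len(nrow(coverage)), coverage$patient_id)
  seq_rows <- list(); dose_rows <- list()
  for (pid in names(by_patient)) {
    cov <- coverage[by_patient[[pid]], , drop = FALSE]
    bps <- sort(unique(c(cov$start, cov$end)))
    n_el <- length(bps) - 1L
    # active regimen on each elementary segment [bps[i], bps[i+1])
    runs <- list()
    for (i in seq_len(n_el)) {
      a <- bps[i]; b <- bps[i + 1L]
      act <- which(cov$start <= a & cov$end >= b)
      if (length(act) == 0L) next
      reg <- regimen_key(cov$ingredient[act])
      last <- if (length(runs)) runs[[length(runs)]] else NULL
      if (!is.null(last) && last$end == a && last$regimen == reg) {
        runs[[length(runs)]]$end <- b
      } else {
        runs[[length(runs) + 1L]] <- list(start = a, end = b, regimen = reg,
                                          cov_rows = act)
      }
    }
    # a regimen can recur over several elementary segments; recompute the
    # covering rows per finished run
    for (k in seq_along(runs)) {
      r <- runs[[k]]
      act <- which(cov$start < r$end & cov$end > r$start)
      ings <- split_regimen(r$regimen)
      dc <- 0L
      for (ing in ings) {
        rows <- act[cov$ingredient[act] == ing]
        trace <- do.call(rbind, cov$dose_trace[rows])
        trace <- trace[order(trace$date), , drop = FALSE]
        inside <- trace$date >= r$start & trace$date < r$end
        before <- which(trace$date < r$start)
        keep <- inside
        if (length(before) > 0L) keep[max(before)] <- TRUE
        doses <- trace$daily_dose[keep]
        if (length(doses) == 0L) doses <- NA_real_
        dc <- dc + (n_distinct_doses(doses) - 1L)
        dose_rows[[length(dose_rows) + 1L]] <- data.frame(
          patient_id = pid, sequence_ordinal = k, ingredient = ing,
          max_dose = if (all(is.na(doses))) NA_real_ else
            max(doses, na.rm = TRUE),
          n_distinct_doses = n_distinct_doses(doses),
          stringsAsFactors = FALSE
        )
      }
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        patient_id = pid, sequence_ordinal = k, regimen = r$regimen,
        n_drugs = length(ings), start = r$start, end = r$end,
        duration_days = as.integer(r$end - r$start), dose_changes = dc,
        stringsAsFactors = FALSE
      )
    }
  }
  seqs <- if (length(seq_rows)) do.call(rbind, seq_rows) else proto
  seqs <- seqs[order(seqs$patient_id, seqs$sequence_ordinal), , drop = FALSE]
  rownames(seqs) <- NULL
  doses <- if (length(dose_rows)) do.call(rbind, dose_rows) else dose_proto
  rownames(doses) <- NULL
  attr(seqs, "doses") <- doses
  seqs
}

#' Attach augmentation agents to treatment sequences
#'
#' An augmentation (lithium, an antipsychotic, thyroxine,
#' tri-iodothyronine or an anticonvulsant added to a treatment sequence)
#' is attached to every sequence its merged coverage overlaps by at least
#' the configured minimum (45 days); an agent spanning two sequences long
#' enough is attached to both.
#'
#' @param seqs Output of [derive_sequences()].
#' @param aug_coverage Augmentation-agent coverage from
#'   [expand_and_merge_coverage()] with `role = "augmentation_agent"`.
#' @param cfg A [study_config()].
#' @return A data frame with columns `patient_id`, `sequence_ordinal`,
#'   `agent`, `agent_class`, `overlap_start`, `overlap_end`,
#'   `overlap_days`.
#' @export
attach_augmentations <- function(seqs, aug_coverage, cfg = study_config()) {
  proto <- data.frame(patient_id = character(), sequence_ordinal = integer(),
                      agent = character(), agent_class = character(),
                      overlap_start = as.Date(character()),
                      overlap_end = as.Date(character()),
                      overlap_days = integer(), stringsAsFactors = FALSE)
  if (nrow(seqs) == 0L || nrow(aug_coverage) == 0L) return(proto)
  out <- list()
  for (i in seq_len(nrow(aug_coverage))) {
    ag <- aug_coverage[i, ]
    cand <- which(seqs$patient_id == ag$patient_id &
                    seqs$start < ag$end & seqs$end > ag$start)
    for (j in cand) {
      os <- max(seqs$start[j], ag$start)
      oe <- min(seqs$end[j], ag$end)
      od <- as.integer(oe - os)
      if (od >= cfg$augmentation_min_days) {
        out[[length(out) + 1L]] <- data.frame(
          patient_id = ag$patient_id,
          sequence_ordinal = seqs$sequence_ordinal[j],
          agent = ag$ingredient, agent_class = ag$agent_class,
          overlap_start = os, overlap_end = oe, overlap_days = od,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) return(proto)
  out <- do.call(rbind, out)
  out <- out[order(out$patient_id, out$sequence_ordinal, out$agent), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
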