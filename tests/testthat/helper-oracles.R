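# Independent reference implementations used only as test oracles.

# Brute-force day-by-day sequence derivation: mark every covered calendar
# day per ingredient, bridge within-ingredient gaps up to the tolerance by
# filling days, then run-length-encode the daily regimen.
brute_sequences <- function(scripts, cfg = study_config()) {
  x <- scripts[scripts$drug_role == "antidepressant" &
                 scripts$issue_date >= cfg$study_start &
                 scripts$issue_date <= cfg$study_end, , drop = FALSE]
  empty <- data.frame(regimen = character(), start = as.Date(character()),
                      end = as.Date(character()), stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(empty)
  limit <- as.integer(cfg$study_end) + 1L
  d0 <- min(as.integer(x$issue_date))
  d1 <- min(max(as.integer(x$issue_date) + x$supply_days), limit)
  ndays <- d1 - d0
  tol <- cfg$same_regimen_gap_tolerance_days
  ings <- sort(unique(x$ingredient))
  onmat <- matrix(FALSE, nrow = ndays, ncol = length(ings),
                  dimnames = list(NULL, ings))
  for (r in seq_len(nrow(x))) {
    s <- as.integer(x$issue_date[r]) - d0 + 1L
    e <- min(as.integer(x$issue_date[r]) + x$supply_days[r], limit) - d0
    onmat[s:e, x$ingredient[r]] <- TRUE
  }
  # bridge per-ingredient gaps of at most tol days
  for (ing in ings) {
    on <- which(onmat[, ing])
    if (length(on) > 1L) {
      gaps <- diff(on)
      for (k in which(gaps > 1L & (gaps - 1L) <= tol)) {
        onmat[(on[k] + 1L):(on[k + 1L] - 1L), ing] <- TRUE
      }
    }
  }
  daily <- apply(onmat, 1L, function(row) paste(ings[row], collapse = "+"))
  runs <- rle(daily)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != ""
  data.frame(
    regimen = runs$values[keep],
    start = as.Date(d0 + starts[keep] - 1L, origin = "1970-01-01"),
    end = as.Date(d0 + ends[keep], origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
}

# Exhaustive pairwise-window reference classifier: every rule evaluated by
# scanning all sequence pairs rather than incrementally.
oracle_classify <- function(seqs, augmentations = NULL, cfg = study_config()) {
  n <- nrow(seqs)
  dur <- seqs$duration_days
  starts <- seqs$start; ends <- seqs$end
  resp <- dur >= cfg$response_min_days

  rem <- logical(n)
  for (i in seq_len(n)) {
    if (dur[i] >= cfg$remission_response_days) { rem[i] <- TRUE; next }
    if (dur[i] < cfg$response_min_days) next
    if (as.integer(cfg$study_end + 1L - ends[i]) < cfg$remission_gap_days) next
    blocked <- FALSE
    for (j in seq_len(n)) {
      if (j != i && starts[j] >= ends[i] &&
          as.integer(starts[j] - ends[i]) < cfg$remission_gap_days) {
        blocked <- TRUE
      }
    }
    rem[i] <- !blocked
  }

  rel <- logical(n)
  rw <- cfg$relapse_window_days
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i == j || starts[i] >= starts[j]) next
    gap <- as.integer(starts[j] - ends[i])
    intervening <- any(starts > ends[i] & starts < starts[j])
    if (resp[i] && !intervening && gap >= rw[1] && gap <= rw[2]) rel[j] <- TRUE
  }

  trans <- rep(NA_character_, n)
  gap <- rep(NA_integer_, n)
  if (n > 1L) for (j in 2:n) {
    gap[j] <- as.integer(starts[j] - ends[j - 1L])
    p <- strsplit(seqs$regimen[j - 1L], "+", fixed = TRUE)[[1]]
    q <- strsplit(seqs$regimen[j], "+", fixed = TRUE)[[1]]
    added <- setdiff(q, p); removed <- setdiff(p, q)
    relapse_pair <- resp[j - 1L] && gap[j] >= rw[1] && gap[j] <= rw[2]
    prior <- seqs$regimen[seq_len(j - 1L)]
    trans[j] <- if (length(removed) == 0L && length(added) > 0L &&
                    dur[j] >= cfg$combination_min_days) "combination"
    else if (length(added) > 0L && length(removed) > 0L &&
             gap[j] >= cfg$switch_gap_min_days &&
             gap[j] <= cfg$switch_gap_max_days) "switch"
    else if (setequal(p, q) && !relapse_pair) "resumption"
    else if (!setequal(p, q) && seqs$regimen[j] %in% prior &&
             !relapse_pair) "resumption"
    else if (length(removed) > 0L && length(added) == 0L)
      "continuation_boundary"
    else "none"
  }

  augd <- logical(n)
  if (!is.null(augmentations) && nrow(augmentations) > 0L) {
    augd[seqs$sequence_ordinal %in% augmentations$sequence_ordinal] <- TRUE
  }
  fail <- logical(n)
  for (i in seq_len(n)) {
    fail[i] <- !resp[i] || augd[i] ||
      (i < n && trans[i + 1L] %in% c("switch", "combination") &&
         gap[i + 1L] <= cfg$episode_gap_days)
  }

  ep <- integer(n); ep[1] <- 1L
  if (n > 1L) for (j in 2:n) {
    ep[j] <- ep[j - 1L] +
      as.integer(gap[j] > cfg$episode_gap_days || rem[j - 1L])
  }
  init <- logical(n)
  for (j in seq_len(n)) {
    init[j] <- j == 1L || ep[j] != ep[j - 1L] ||
      trans[j] %in% c("switch", "combination")
  }
  lines <- max(vapply(unique(ep), function(e) {
    length(unique(seqs$regimen[ep == e & init]))
  }, integer(1)))
  trd <- any(vapply(unique(ep), function(e) {
    idx <- ep == e & fail & init & dur >= cfg$adequate_line_min_days
    length(unique(seqs$regimen[idx])) >= 2L
  }, logical(1)))

  list(response = resp, remission = rem, relapse = rel, transition = trans,
       failure = fail, lines = lines,
       group = if (trd) "TRD" else "MDD")
}
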