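#' Study configuration
#'
#' All observation-window bounds and rule thresholds used by the pathway
#' derivation live in one place. Defaults reproduce the operational
#' definitions of the source study: a 2015-2020 observation window,
#' exclusion codes screened from 2010 onwards, a 30-day default script
#' length, response at >= 90 days of a constant regimen, remission at
#' >= 180 days or a >= 90-day sequence followed by 60 antidepressant-free
#' days, a 60-180 day relapse/switch window (endpoints inclusive), and a
#' 45-day minimum for combination and augmentation.
#'
#' @param study_start,study_end Date bounds of the observation window.
#' @param exclusion_lookback_start Exclusion diagnoses (bipolar, dementia,
#'   mania, psychosis, schizophrenia/schizoaffective) recorded on or after
#'   this date make a patient ineligible.
#' @param default_supply_days Supply length imputed when a script has no
#'   recorded quantity (days).
#' @param response_min_days Minimum sequence duration for treatment
#'   response (days).
#' @param remission_response_days Sequence duration that on its own
#'   qualifies as remission (days).
#' @param remission_gap_days Antidepressant-free look-forward after a
#'   responding sequence that qualifies as remission (days). The window is
#'   half-open: a new script exactly `remission_gap_days` after the
#'   sequence end does not block remission.
#' @param relapse_window_days Length-2 integer vector; a new sequence
#'   starting within this many days (inclusive at both ends) after the end
#'   of a responding sequence is a relapse.
#' @param switch_gap_min_days,switch_gap_max_days Gap window for classifying
#'   a regimen replacement as a switch. The study definition tolerates
#'   delays of 60-180 days; by default immediate replacements (gap < 60,
#'   including same-day) are also counted as switches, since a replacement
#'   with no gap is unambiguously a switch. Set `switch_gap_min_days = 60`
#'   for the literal windowed behaviour.
#' @param combination_min_days Minimum duration of the enlarged regimen for
#'   a combination (days).
#' @param augmentation_min_days Minimum overlap of an augmentation agent
#'   with a sequence (days).
#' @param adequate_line_min_days Minimum sequence duration for a failed
#'   line to count towards treatment resistance (days). The source
#'   definition requires "adequate duration" without a number; the default
#'   of 42 days matches the 4-6 week review cadence in national guidance.
#' @param same_regimen_gap_tolerance_days Same-ingredient coverage gaps up
#'   to this length are bridged when building coverage intervals, and a
#'   between-sequence gap must exceed it to split otherwise-identical
#'   regimens. Chosen equal to the remission look-forward so that a gap
#'   short enough not to signal remission also does not fragment a
#'   sequence.
#' @param episode_gap_days A treatment-free gap strictly greater than this
#'   closes a depressive episode for line counting (a relapse at exactly
#'   the upper relapse bound stays within its episode).
#' @param month_length_days Days per month used for all day-to-month
#'   conversions.
#' @param suppression_ceiling Counts strictly below this are suppressed as
#'   `"<5"` in aggregate tables.
#' @param rng_seed Seed recorded into run manifests.
#'
#' @return An object of class `study_config` (a validated named list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$response_min_days
study_config <- function(study_start = as.Date("2015-01-01"),
                         study_end = as.Date("2020-12-31"),
                         exclusion_lookback_start = as.Date("2010-01-01"),
                         default_supply_days = 30L,
                         response_min_days = 90L,
                         remission_response_days = 180L,
                         remission_gap_days = 60L,
                         relapse_window_days = c(60L, 180L),
                         switch_gap_min_days = 0L,
                         switch_gap_max_days = 180L,
                         combination_min_days = 45L,
                         augmentation_min_days = 45L,
                         adequate_line_min_days = 42L,
                         same_regimen_gap_tolerance_days = 60L,
                         episode_gap_days = 180L,
                         month_length_days = 30.44,
                         suppression_ceiling = 5L,
                         rng_seed = 1L) {
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    exclusion_lookback_start = as.Date(exclusion_lookback_start),
    default_supply_days = as.integer(default_supply_days),
    response_min_days = as.integer(response_min_days),
    remission_response_days = as.integer(remission_response_days),
    remission_gap_days = as.integer(remission_gap_days),
    relapse_window_days = as.integer(relapse_window_days),
    switch_gap_min_days = as.integer(switch_gap_min_days),
    switch_gap_max_days = as.integer(switch_gap_max_days),
    combination_min_days = as.integer(combination_min_days),
    augmentation_min_days = as.integer(augmentation_min_days),
    adequate_line_min_days = as.integer(adequate_line_min_days),
    same_regimen_gap_tolerance_days = as.integer(same_regimen_gap_tolerance_days),
    episode_gap_days = as.integer(episode_gap_days),
    month_length_days = as.numeric(month_length_days),
    suppression_ceiling = as.integer(suppression_ceiling),
    rng_seed = as.integer(rng_seed)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  stopifnot(
    !is.na(cfg$study_start), !is.na(cfg$study_end),
    cfg$study_start < cfg$study_end,
    cfg$default_supply_days >= 1L,
    cfg$response_min_days > 0L,
    cfg$remission_response_days > 0L,
    cfg$remission_gap_days > 0L,
    length(cfg$relapse_window_days) == 2L,
    all(cfg$relapse_window_days > 0L),
    cfg$relapse_window_days[1L] < cfg$relapse_window_days[2L],
    cfg$switch_gap_min_days >= 0L,
    cfg$switch_gap_max_days > cfg$switch_gap_min_days,
    cfg$combination_min_days > 0L,
    cfg$augmentation_min_days > 0L,
    cfg$adequate_line_min_days > 0L,
    cfg$same_regimen_gap_tolerance_days > 0L,
    cfg$episode_gap_days > 0L,
    cfg$month_length_days > 0,
    cfg$suppression_ceiling >= 1L
  )
  invisible(cfg)
}

#' Read a study configuration from a YAML file
#'
#' Keys mirror the arguments of [study_config()]; unknown keys are an
#' error, missing keys take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    stop("unknown study_config keys: ", paste(extra, collapse = ", "))
  }
  for (key in c("study_start", "study_end", "exclusion_lookback_start")) {
    if (!is.null(raw[[key]])) raw[[key]] <- as.Date(raw[[key]])
  }
  do.call(study_config, raw)
}

#' Write a study configuration to a YAML file
#'
#' @param cfg A `study_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(cfg, path) {
  out <- unclass(cfg)
  for (key in c("study_start", "study_end", "exclusion_lookback_start")) {
    out[[key]] <- format(out[[key]], "%Y-%m-%d")
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  window: %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  response >= %d d; remission >= %d d or %d-d drug-free gap\n",
              x$response_min_days, x$remission_response_days,
              x$remission_gap_days))
  cat(sprintf("  relapse window: %d-%d d (inclusive)\n",
              x$relapse_window_days[1], x$relapse_window_days[2]))
  cat(sprintf("  combination/augmentation >= %d/%d d; adequate line >= %d d\n",
              x$combination_min_days, x$augmentation_min_days,
              x$adequate_line_min_days))
  cat(sprintf("  coverage gap tolerance: %d d; episode gap: > %d d\n",
              x$same_regimen_gap_tolerance_days, x$episode_gap_days))
  invisible(x)
}
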