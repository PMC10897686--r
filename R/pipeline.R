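#' Run the full pipeline: simulate/read, screen, classify, report
#'
#' Orchestrates the stages end to end: obtain inputs (either simulate a
#' synthetic cohort or read the four CSV files from `input_dir`), build
#' the eligibility-screened cohort, derive sequences and pathway events,
#' compute per-patient metrics, produce suppressed group summary tables
#' and the standard group comparisons, and write everything to `out_dir`
#' together with a run manifest (config, seed, file checksums, row counts
#' per stage). Given a fixed configuration and seed, all analysis outputs
#' are byte-identical across runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param input_dir Directory containing `prescriptions.csv`,
#'   `events.csv`, `contacts.csv`, `demographics.csv`; NULL to simulate.
#' @param gen_cfg A [generator_config()] used when simulating.
#' @param cfg A [study_config()].
#' @param dict A code dictionary.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, input_dir = NULL,
                         gen_cfg = generator_config(),
                         cfg = study_config(),
                         dict = default_code_dictionary()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulated <- is.null(input_dir)
  if (simulated) {
    input_dir <- file.path(out_dir, "inputs")
    generate_cohort(gen_cfg, dict, cfg, out_dir = input_dir)
  }
  paths <- c(prescriptions = file.path(input_dir, "prescriptions.csv"),
             events = file.path(input_dir, "events.csv"),
             contacts = file.path(input_dir, "contacts.csv"),
             demographics = file.path(input_dir, "demographics.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input stage failure: missing file(s): ",
         paste(missing, collapse = ", "))
  }
  prescriptions <- read_prescriptions(paths["prescriptions"], dict, cfg)
  events <- read_clinical_events(paths["events"], dict)
  contacts <- read_contacts(paths["contacts"])
  demographics <- read_demographics(paths["demographics"])

  cohort <- build_cohort(prescriptions, events, demographics, cfg)
  pathways <- derive_pathways(prescriptions, events, contacts, cohort,
                              dict, cfg)
  metrics <- compute_patient_metrics(pathways, prescriptions, events,
                                     contacts, cohort, cfg)
  summary <- summarize_groups(metrics, pathways$classifications)
  rendered <- render_summary_tables(summary, cfg)

  # standard group comparisons (categorical via chi-square, numeric via
  # rank-sum), on the MDD vs TRD split
  m <- merge(metrics,
             pathways$classifications[, c("patient_id", "group")],
             by = "patient_id")
  m$responded <- m$n_responses >= 1L
  m$relapsed <- m$n_relapses >= 1L
  comparisons <- list()
  for (metric in c("remission_flag", "responded", "relapsed")) {
    comparisons[[metric]] <- tryCatch(
      unclass(compare_groups(m, metric)), error = function(e) {
        list(error = conditionMessage(e))
      })
  }
  for (metric in c("n_prescriptions", "months_in_study",
                   "time_to_mhs_contact_months")) {
    comparisons[[metric]] <- tryCatch(
      unclass(compare_groups(m, metric)), error = function(e) {
        list(error = conditionMessage(e))
      })
  }

  out_paths <- c(cohort = file.path(out_dir, "cohort.csv"),
                 sequences = file.path(out_dir, "sequences.csv"),
                 pathway_events = file.path(out_dir, "pathway_events.csv"),
                 classifications = file.path(out_dir, "classifications.csv"),
                 patient_metrics = file.path(out_dir, "patient_metrics.csv"),
                 summary_stats = file.path(out_dir, "summary_stats.csv"),
                 summary_rates = file.path(out_dir, "summary_rates.csv"),
                 summary_counts = file.path(out_dir, "summary_counts.csv"))
  write_records(cohort, out_paths["cohort"])
  write_records(pathways$sequences, out_paths["sequences"])
  write_records(pathways$events, out_paths["pathway_events"])
  write_records(pathways$classifications, out_paths["classifications"])
  write_records(metrics, out_paths["patient_metrics"])
  write_records(rendered$stats, out_paths["summary_stats"])
  write_records(rendered$rates, out_paths["summary_rates"])
  write_records(rendered$counts, out_paths["summary_counts"])
  jsonlite::write_json(comparisons, file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rxpathways")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (simulated) gen_cfg$rng_seed else NA_integer_,
    simulated = simulated,
    study_config = lapply(unclass(cfg), function(v) {
      if (inherits(v, "Date")) format(v, "%Y-%m-%d") else v
    }),
    input_checksums = as.list(stats::setNames(
      tools::md5sum(unname(paths)), basename(unname(paths)))),
    output_checksums = as.list(stats::setNames(
      tools::md5sum(unname(c(out_paths,
                             file.path(out_dir, "comparisons.json")))),
      c(basename(unname(out_paths)), "comparisons.json"))),
    row_counts = list(
      prescriptions = nrow(prescriptions),
      prescriptions_rejected = attr(prescriptions, "n_rejected") %||% 0L,
      events = nrow(events),
      contacts = nrow(contacts),
      demographics = nrow(demographics),
      patients = nrow(cohort),
      eligible = sum(cohort$eligible),
      sequences = nrow(pathways$sequences),
      pathway_events = nrow(pathways$events),
      classifications = nrow(pathways$classifications),
      metrics = nrow(metrics)
    )
  )
  if (manifest$row_counts$classifications != manifest$row_counts$eligible) {
    stop("patient loss between cohort and classification stages")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
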