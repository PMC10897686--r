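cfg <- study_config()
dict <- test_dict()

test_that("time to first mental-health contact uses the earliest route", {
  ev <- rbind(event_rows("P", "depression", 0, base = as.Date("2015-01-01")),
              event_rows("P", "mhs_referral", 0, base = as.Date("2018-06-01")))
  expect_equal(time_to_first_mhs_contact(ev, NULL, cfg),
               1247 / 30.44, tolerance = 1e-10)
  # contact record without any referral code still counts (non-GP routes)
  ev2 <- event_rows("P", "depression", 0, base = as.Date("2015-01-01"))
  ct <- data.frame(patient_id = "P", contact_date = as.Date("2016-01-01"),
                   setting = "a_and_e", stringsAsFactors = FALSE)
  expect_equal(time_to_first_mhs_contact(ev2, ct, cfg), 365 / 30.44,
               tolerance = 1e-10)
  # no contact at all
  expect_true(is.na(time_to_first_mhs_contact(ev2, NULL, cfg)))
  # contact predating the code: negative, with a warning
  ct_early <- data.frame(patient_id = "P",
                         contact_date = as.Date("2014-06-01"),
                         setting = "outpatient", stringsAsFactors = FALSE)
  expect_warning(d <- time_to_first_mhs_contact(ev2, ct_early, cfg),
                 "predates")
  expect_lt(d, 0)
})

make_bundle <- function(rx, ev, ct = NULL) {
  f <- tempfile(); write_records(rx, f)
  rx2 <- read_prescriptions(f, dict, cfg)
  coh <- build_cohort(rx2, ev, data.frame(
    patient_id = unique(rx$patient_id),
    date_of_birth = as.Date("1980-01-01"), gender = "F",
    stringsAsFactors = FALSE), cfg)
  pw <- derive_pathways(rx2, ev, ct, coh, dict, cfg)
  met <- compute_patient_metrics(pw, rx2, ev, ct, coh, cfg)
  list(cohort = coh, pathways = pw, metrics = met)
}

test_that("patient metrics tally scripts, resumptions and durations", {
  # 10 scripts of one drug in 3 bursts separated by >180-day breaks:
  # two resumptions, response only in the final burst
  rx <- rx_rows("P", "citalopram",
                c(0, 30, 250, 280, 500, 530, 560, 590, 620, 650))
  ev <- event_rows("P", "depression", -120)
  b <- make_bundle(rx, ev)
  m <- b$metrics
  expect_equal(m$n_prescriptions, 10L)
  expect_equal(m$n_resumptions, 2L)
  expect_equal(m$months_in_study,
               as.integer(cfg$study_end - BASE_DATE) / 30.44,
               tolerance = 1e-10)
  # final burst responds 90 days after day 500: depression ran 710 days
  expect_equal(m$duration_of_depression_months, 710 / 30.44,
               tolerance = 1e-10)
  expect_equal(m$suicidality_record_count, 0L)
})

test_that("duration of depression runs to study end without a response", {
  rx <- rx_rows("P", "citalopram", c(0, 30))  # 60 days, no response
  ev <- event_rows("P", "depression", -100)
  b <- make_bundle(rx, ev)
  expect_equal(b$metrics$duration_of_depression_months,
               as.integer(cfg$study_end - (BASE_DATE - 100L)) / 30.44,
               tolerance = 1e-10)
})

test_that("small counts are suppressed totally and idempotently", {
  expect_equal(suppress_small_counts(3L, cfg), "<5")
  expect_equal(suppress_small_counts(0L, cfg), "<5")
  expect_equal(suppress_small_counts(5L, cfg), "5")
  expect_equal(suppress_small_counts(c(4L, 5L, 123L), cfg),
               c("<5", "5", "123"))
  expect_error(suppress_small_counts(-1L, cfg), "negative")
  # idempotent on data frames; character columns pass through
  df <- data.frame(g = c("a", "b"), n = c(2L, 10L), rate = c(1.5, 2.5))
  once <- suppress_small_counts(df, cfg)
  expect_equal(once$n, c("<5", "10"))
  expect_equal(once$rate, c(1.5, 2.5))  # non-integer column untouched
  expect_identical(suppress_small_counts(once, cfg), once)
})

test_that("no rendered table cell is a bare integer in the suppressed range", {
  set.seed(5)
  for (rep in 1:20) {
    tab <- data.frame(group = letters[1:4],
                      n = sample(0:20, 4),
                      events = sample(0:8, 4))
    out <- suppress_small_counts(tab, cfg)
    cells <- unlist(out[, c("n", "events")])
    bare <- suppressWarnings(as.integer(cells))
    expect_false(any(!is.na(bare) & bare >= 1L & bare <= 4L))
    expect_true(all(is.na(bare) == (cells == "<5")))
  }
})

test_that("group summaries are sane, overlap-aware and order-invariant", {
  gc <- generator_config(n_patients = 150L, rng_seed = 303L)
  syn <- generate_cohort(gc, dict, cfg, out_dir = tempdir())
  rx <- read_prescriptions(file.path(tempdir(), "prescriptions.csv"),
                           dict, cfg)
  ev <- read_clinical_events(file.path(tempdir(), "events.csv"), dict)
  ct <- read_contacts(file.path(tempdir(), "contacts.csv"))
  dm <- read_demographics(file.path(tempdir(), "demographics.csv"))
  coh <- build_cohort(rx, ev, dm, cfg)
  pw <- derive_pathways(rx, ev, ct, coh, dict, cfg)
  met <- compute_patient_metrics(pw, rx, ev, ct, coh, cfg)
  s <- summarize_groups(met, pw$classifications)
  n_of <- function(g) s$counts$n[s$counts$group == g]
  expect_equal(n_of("MDD") + n_of("TRD"), n_of("Overall"))
  expect_lte(n_of("TRD4+"), n_of("TRD3+"))
  expect_lte(n_of("TRD3+"), n_of("TRD"))
  # the contact subgroup straddles both diagnostic groups
  expect_lte(n_of("MHS"), n_of("Overall"))
  # permutation invariance in patient order
  perm <- sample(nrow(met))
  s2 <- summarize_groups(met[perm, ], pw$classifications)
  expect_equal(s$stats$mean, s2$stats$mean)
  expect_equal(s$rates$count, s2$rates$count)
  # rendered tables carry no unsuppressed small integers
  r <- render_summary_tables(s, cfg)
  for (col in c("n")) {
    bare <- suppressWarnings(as.integer(r$stats[[col]]))
    expect_false(any(!is.na(bare) & bare >= 1L & bare <= 4L))
  }
  # a degenerate empty group never divides by zero
  expect_true(all(is.finite(s$rates$pct) | is.na(s$rates$pct)))
})

test_that("identical patients give zero spread", {
  df <- data.frame(patient_id = c("A", "B", "C"),
                   months_in_study = 10,
                   duration_of_depression_months = 5,
                   time_to_mhs_contact_months = NA_real_,
                   n_prescriptions = 7L, n_resumptions = 0L,
                   n_combination_prescriptions = 0L,
                   n_augmentation_prescriptions = 0L,
                   n_responses = 1L, n_relapses = 0L,
                   remission_flag = TRUE, suicidality_record_count = 0L,
                   stringsAsFactors = FALSE)
  cls <- data.frame(patient_id = c("A", "B", "C"), group = "MDD",
                    trd_3plus_lines = FALSE, trd_4plus_lines = FALSE,
                    mhs_contact = FALSE, stringsAsFactors = FALSE)
  s <- summarize_groups(df, cls)
  row <- s$stats[s$stats$group == "MDD" &
                   s$stats$metric == "n_prescriptions", ]
  expect_equal(row$mean, 7)
  expect_equal(row$sd, 0)
})
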