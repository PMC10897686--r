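cfg <- study_config()
dict <- test_dict()

test_that("response requires 90 days; dose changes do not disqualify", {
  expect_true(detect_response(seqs_of(rx_rows("P", "citalopram",
                                              c(0, 30, 60)), cfg), cfg))
  expect_false(detect_response(seqs_of(rx_rows("P", "citalopram",
                                               c(0, 30, 59)), cfg), cfg))
  # dose changes count distinct dose values minus one
  s <- seqs_of(rx_rows("P", "citalopram", c(0, 30, 60, 90),
                       dose = c(20, 40, 20, 40)), cfg)
  expect_equal(s$dose_changes, 1L)
  expect_true(detect_response(s, cfg))
})

test_that("remission fires by duration or by a 60-day drug-free gap", {
  # 200-day sequence: duration clause
  s <- seqs_of(rx_rows("P", "citalopram", seq(0, 170, 30)), cfg)
  r <- detect_remission(s, cfg)
  expect_true(r)
  expect_equal(attr(r, "clause"), "duration")
  # 100-day sequence, next script 61 days later: gap clause
  s2 <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 70)),
                      rx_rows("P", "sertraline", 161)), cfg)
  r2 <- detect_remission(s2, cfg)
  expect_equal(as.logical(r2), c(TRUE, FALSE))
  expect_equal(attr(r2, "clause")[1], "gap")
  # next script 30 days later: blocked
  s3 <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 70)),
                      rx_rows("P", "sertraline", 130)), cfg)
  expect_equal(as.logical(detect_remission(s3, cfg)), c(FALSE, FALSE))
})

test_that("ongoing treatment censored at the study end is not a gap remission", {
  # 100-day sequence ending 10 days before the study end: the 60-day
  # drug-free window is unobservable
  rx <- rx_rows("P", "citalopram", c(0, 30, 70),
                base = cfg$study_end - 110L)
  s <- seqs_of(rx, cfg)
  expect_true(detect_response(s, cfg))
  expect_false(any(detect_remission(s, cfg)))
})

test_that("relapse window is inclusive at 60 and 180 days", {
  make <- function(gap) {
    seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 70)),
                  rx_rows("P", "sertraline", 100 + gap)), cfg)
  }
  for (gap in c(59L, 60L, 61L, 179L, 180L, 181L)) {
    rel <- detect_relapse(make(gap), cfg)
    expect_equal(any(rel), gap >= 60L && gap <= 180L,
                 info = paste("gap", gap))
  }
  # no relapse without a prior response
  s <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30)),  # 60 d, no resp.
                     rx_rows("P", "sertraline", 150)), cfg)
  expect_false(any(detect_relapse(s, cfg)))
})

test_that("transitions classify switch, combination, resumption by precedence", {
  # sertraline then citalopram starting 70 days after stop: switch
  s <- seqs_of(rbind(rx_rows("P", "sertraline", c(0, 30, 60)),
                     rx_rows("P", "citalopram", 160)), cfg)
  expect_equal(classify_transition(s[1, ], s[2, ], cfg), "switch")
  # citalopram then citalopram+mirtazapine held 50 days: combination
  s2 <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 60, 80)),
                      rx_rows("P", "mirtazapine", c(60, 80))), cfg)
  expect_equal(classify_transition(s2[1, ], s2[2, ], cfg), "combination")
  # fluoxetine restarted after a 200-day break: resumption
  s3 <- seqs_of(rbind(rx_rows("P", "fluoxetine", c(0, 30, 60)),
                      rx_rows("P", "fluoxetine", 290)), cfg)
  expect_equal(classify_transition(s3[1, ], s3[2, ], cfg), "resumption")
  # drug dropped from a combination, nothing added
  s4 <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 60, 90)),
                      rx_rows("P", "mirtazapine", c(0, 30))), cfg)
  expect_equal(classify_transition(s4[1, ], s4[2, ], cfg),
               "continuation_boundary")
  # overlapping sequences are a construction bug
  fake <- s4; fake$start[2] <- fake$start[1]
  expect_error(classify_transition(fake[1, ], fake[2, ], cfg), "overlap")
})

test_that("the literal windowed switch definition is available via config", {
  cfg_lit <- study_config(switch_gap_min_days = 60L)
  s <- seqs_of(rbind(rx_rows("P", "sertraline", c(0, 30)),
                     rx_rows("P", "citalopram", 70)), cfg)  # 10-day gap
  expect_equal(classify_transition(s[1, ], s[2, ], cfg), "switch")
  expect_equal(classify_transition(s[1, ], s[2, ], cfg_lit), "none")
})

test_that("combination requires the enlarged regimen for 45 days", {
  make <- function(hold) {
    seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 60, 60 + hold - 30)),
                  rx_rows("P", "mirtazapine", c(60, 60 + hold - 30))), cfg)
  }
  for (hold in c(44L, 45L, 46L)) {
    s <- make(hold)
    expect_equal(classify_transition(s[1, ], s[2, ], cfg) == "combination",
                 hold >= 45L, info = paste("hold", hold))
  }
})

test_that("treatment failure covers non-response, change, and augmentation", {
  # 60-day sequence then switch: failed twice over
  s <- seqs_of(rbind(rx_rows("P", "sertraline", c(0, 30)),
                     rx_rows("P", "citalopram", c(70, 100, 130, 160))), cfg)
  expect_equal(detect_treatment_failure(s, cfg = cfg), c(TRUE, FALSE))
  # 200-day sequence, nothing after: not a failure
  s2 <- seqs_of(rx_rows("P", "citalopram", seq(0, 170, 30)), cfg)
  expect_false(detect_treatment_failure(s2, cfg = cfg))
  # 120-day responding sequence with >= 45 days of lithium: failed anyway
  s3 <- seqs_of(rx_rows("P", "citalopram", c(0, 30, 60, 90)), cfg)
  aug <- attach_augmentations(
    s3, expand_and_merge_coverage(rx_rows("P", "lithium", 10, supply = 50L),
                                  cfg, role = "augmentation_agent"), cfg)
  expect_true(detect_treatment_failure(s3, aug, cfg))
})

test_that("line counting follows initiations, not resumptions", {
  # start A, switch to B, combine B+C (held 45 days): 3 lines
  s <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30)),
                     rx_rows("P", "sertraline", c(70, 100, 130, 145)),
                     rx_rows("P", "mirtazapine", c(130, 160))), cfg)
  expect_equal(count_lines(s, cfg = cfg), 3L)
  # start A, resume A twice: 1 line
  s2 <- seqs_of(rx_rows("P", "citalopram", c(0, 100, 200)), cfg)
  expect_equal(nrow(s2), 3L)  # 70- and 100-day gaps split sequences
  expect_equal(count_lines(s2, cfg = cfg), 1L)
  expect_equal(count_lines(seqs_of(rx_rows("P", "citalopram", 0), cfg),
                           cfg = cfg), 1L)
})

test_that("two adequate failed distinct lines in one episode mean TRD", {
  # sertraline 60 d failed by switch, citalopram 50 d failed by
  # combination: resistant with 3 lines
  s <- seqs_of(rbind(rx_rows("P", "sertraline", c(0, 30)),
                     rx_rows("P", "citalopram", c(70, 100, 130)),
                     rx_rows("P", "mirtazapine", c(115, 145))), cfg)
  expect_equal(s$regimen, c("sertraline", "citalopram",
                            "citalopram+mirtazapine", "mirtazapine"))
  res <- classify_patient(s, dict = dict, cfg = cfg)
  expect_equal(res$classification$group, "TRD")
  expect_equal(res$classification$lines_of_therapy, 3L)
  # one responding, remitting sequence: MDD
  s2 <- seqs_of(rx_rows("P", "citalopram", seq(0, 170, 30)), cfg)
  expect_equal(classify_patient(s2, dict = dict,
                                cfg = cfg)$classification$group, "MDD")
  # two failed lines separated by 200 treatment-free days: different
  # episodes, so MDD
  s3 <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30)),
                      rx_rows("P", "sertraline", c(260, 290))), cfg)
  expect_equal(classify_patient(s3, dict = dict,
                                cfg = cfg)$classification$group, "MDD")
})

test_that("remission and relapse never contradict on a sequence pair", {
  # for any follow-on gap, a relapse (gap in [60, 180]) implies the
  # responding sequence ended with an observable drug-free window
  for (gap in c(59L, 60L, 61L, 179L, 180L, 181L)) {
    s <- seqs_of(rbind(rx_rows("P", "citalopram", c(0, 30, 70)),
                       rx_rows("P", "sertraline", 100 + gap)), cfg)
    rel <- any(detect_relapse(s, cfg))
    rem <- detect_remission(s, cfg)[1]
    if (rel) expect_true(gap >= 60L)
    if (gap < 60L) expect_false(rem)  # drug-free window violated
  }
})

test_that("classifier agrees exactly with the pairwise-window oracle", {
  set.seed(7)
  checked <- 0L
  for (rep in 1:200) {
    rx <- random_scripts(sprintf("P%03d", rep))
    s <- seqs_of(rx, cfg)
    if (nrow(s) == 0L || nrow(s) > 4L) next
    checked <- checked + 1L
    res <- classify_patient(s, cfg = cfg)
    want <- oracle_classify(s, cfg = cfg)
    expect_equal(res$classification$group, want$group,
                 info = paste("patient", rep))
    expect_equal(res$classification$lines_of_therapy, want$lines,
                 info = paste("patient", rep))
    expect_equal(res$classification$n_responses, sum(want$response),
                 info = paste("patient", rep))
    expect_equal(res$classification$n_relapses, sum(want$relapse),
                 info = paste("patient", rep))
    expect_equal(res$classification$failure_count, sum(want$failure),
                 info = paste("patient", rep))
    expect_equal(sum(res$events$event_type == "remission"),
                 sum(want$remission), info = paste("patient", rep))
  }
  expect_gt(checked, 100L)
})

test_that("subgroup flags nest and imply resistance", {
  arc <- generate_archetypes(dict)
  f <- tempfile(); write_records(arc$prescriptions, f)
  rx <- read_prescriptions(f, dict, cfg)
  coh <- data.frame(patient_id = unique(rx$patient_id), eligible = TRUE,
                    stringsAsFactors = FALSE)
  pw <- derive_pathways(rx, cohort = coh, dict = dict, cfg = cfg)
  cls <- pw$classifications
  expect_true(all(!cls$trd_4plus_lines | cls$trd_3plus_lines))
  expect_true(all(!cls$trd_3plus_lines | cls$group == "TRD"))
  expect_true(all(cls$lines_of_therapy[cls$group == "TRD"] >= 2L))
})
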