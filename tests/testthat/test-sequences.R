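cfg <- study_config()

test_that("coverage merges gaps up to the tolerance and not beyond", {
  # 30-day scripts on 2016-01-01 and 2016-02-05: 5-day gap, one interval
  rx <- rx_rows("P1", "citalopram", c(0, 35), base = as.Date("2016-01-01"))
  cov <- expand_and_merge_coverage(rx, cfg)
  expect_equal(nrow(cov), 1L)
  expect_equal(cov$start, as.Date("2016-01-01"))
  expect_equal(cov$end, as.Date("2016-03-06"))

  # scripts 91 days apart: 61-day gap exceeds the 60-day tolerance
  rx2 <- rx_rows("P1", "citalopram", c(0, 91))
  expect_equal(nrow(expand_and_merge_coverage(rx2, cfg)), 2L)
  # exactly 60-day gap still merges
  rx3 <- rx_rows("P1", "citalopram", c(0, 90))
  expect_equal(nrow(expand_and_merge_coverage(rx3, cfg)), 1L)

  # single script: one default-length interval
  cov1 <- expand_and_merge_coverage(rx_rows("P1", "citalopram", 0), cfg)
  expect_equal(as.integer(cov1$end - cov1$start), 30L)
})

test_that("overlapping same-drug scripts extend but never stack supply", {
  rx <- rx_rows("P1", "citalopram", c(0, 10, 20))
  cov <- expand_and_merge_coverage(rx, cfg)
  expect_equal(as.integer(cov$end - cov$start), 50L)  # max end, not 90
})

test_that("dose changes never split a sequence; regimen changes always do", {
  # 120 days of citalopram with a dose increase at day 30
  rx <- rx_rows("P1", "citalopram", c(0, 30, 60, 90),
                dose = c(20, 40, 40, 40))
  s <- seqs_of(rx, cfg)
  expect_equal(nrow(s), 1L)
  expect_equal(s$regimen, "citalopram")
  expect_equal(s$dose_changes, 1L)
  expect_equal(s$duration_days, 120L)

  # citalopram days 0-90, mirtazapine added days 50-140: three sequences
  rx2 <- rbind(rx_rows("P2", "citalopram", c(0, 30, 60)),
               rx_rows("P2", "mirtazapine", c(50, 80, 110)))
  s2 <- seqs_of(rx2, cfg)
  expect_equal(s2$regimen,
               c("citalopram", "citalopram+mirtazapine", "mirtazapine"))
  expect_equal(as.integer(s2$start - BASE_DATE), c(0L, 50L, 90L))
  expect_equal(as.integer(s2$end - BASE_DATE), c(50L, 90L, 140L))
  expect_equal(s2$sequence_ordinal, 1:3)

  expect_equal(nrow(seqs_of(rx_rows("P1", "citalopram", integer()), cfg)), 0L)
})

test_that("missing doses compare equal to missing and unequal to numbers", {
  rx <- rx_rows("P1", "citalopram", c(0, 30, 60), dose = c(NA, NA, NA))
  expect_equal(seqs_of(rx, cfg)$dose_changes, 0L)
  rx2 <- rx_rows("P1", "citalopram", c(0, 30, 60), dose = c(20, NA, 20))
  expect_equal(seqs_of(rx2, cfg)$dose_changes, 1L)
})

test_that("augmentation attachment respects the 45-day overlap rule", {
  base_rx <- rx_rows("P1", "sertraline", seq(0, 180, by = 30))  # 210 d
  s <- seqs_of(base_rx, cfg)
  # lithium covering 50 days inside the sequence: attached
  aug50 <- expand_and_merge_coverage(
    rx_rows("P1", "lithium", 20, supply = 50L), cfg,
    role = "augmentation_agent")
  got <- attach_augmentations(s, aug50, cfg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$agent_class, "lithium")
  expect_equal(got$overlap_days, 50L)
  # 44-day overlap: not attached
  aug44 <- expand_and_merge_coverage(
    rx_rows("P1", "quetiapine", 20, supply = 44L), cfg,
    role = "augmentation_agent")
  expect_equal(nrow(attach_augmentations(s, aug44, cfg)), 0L)

  # agent overlapping two sequences by >= 45 days each: attached to both
  rx2 <- rbind(rx_rows("P2", "citalopram", c(0, 30)),
               rx_rows("P2", "sertraline", c(60, 90, 120)))
  s2 <- seqs_of(rx2, cfg)
  agent <- expand_and_merge_coverage(
    rbind(rx_rows("P2", "lithium", 0, supply = 60L),
          rx_rows("P2", "lithium", 60, supply = 60L)), cfg,
    role = "augmentation_agent")
  both <- attach_augmentations(s2, agent, cfg)
  expect_equal(nrow(both), 2L)
  expect_setequal(both$sequence_ordinal, c(1L, 2L))
})

test_that("person-time is conserved between coverage and sequences", {
  set.seed(42)
  for (rep in 1:50) {
    rx <- random_scripts(sprintf("P%02d", rep))
    cov <- expand_and_merge_coverage(rx, cfg)
    s <- derive_sequences(cov, cfg)
    # union of coverage days equals union of sequence days
    cov_days <- unique(unlist(mapply(function(a, b) seq(a, b - 1L),
                                     as.integer(cov$start),
                                     as.integer(cov$end),
                                     SIMPLIFY = FALSE)))
    seq_days <- unlist(mapply(function(a, b) seq(a, b - 1L),
                              as.integer(s$start), as.integer(s$end),
                              SIMPLIFY = FALSE))
    expect_equal(sort(cov_days), sort(seq_days))
    expect_equal(anyDuplicated(seq_days), 0L)
  }
})

test_that("sequence engine matches the day-by-day oracle on random patients", {
  set.seed(99)
  for (rep in 1:100) {
    rx <- random_scripts(sprintf("P%03d", rep))
    got <- seqs_of(rx, cfg)
    want <- brute_sequences(rx, cfg)
    expect_equal(got$regimen, want$regimen, info = paste("patient", rep))
    expect_equal(got$start, want$start, info = paste("patient", rep))
    expect_equal(got$end, want$end, info = paste("patient", rep))
  }
})
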