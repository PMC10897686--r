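cfg <- study_config()
dict <- test_dict()

test_that("generation is deterministic: same seed, byte-identical files", {
  gc <- generator_config(n_patients = 60L, rng_seed = 99L)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  generate_cohort(gc, dict, cfg, out_dir = d1)
  generate_cohort(gc, dict, cfg, out_dir = d2)
  for (f in c("prescriptions.csv", "events.csv", "contacts.csv",
              "demographics.csv", "truth.csv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the data
  gc2 <- generator_config(n_patients = 60L, rng_seed = 100L)
  d3 <- file.path(tempfile(), "c")
  generate_cohort(gc2, dict, cfg, out_dir = d3)
  expect_false(unname(tools::md5sum(file.path(d1, "prescriptions.csv"))) ==
                 unname(tools::md5sum(file.path(d3, "prescriptions.csv"))))
})

test_that("zero resistance proportion yields an all-MDD truth table", {
  gc <- generator_config(n_patients = 80L, trd_proportion = 0,
                         rng_seed = 17L)
  syn <- generate_cohort(gc, dict, cfg)
  expect_true(all(syn$truth$true_group == "MDD"))
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(generator_config(trd_proportion = 1.2), "probability")
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(drug_weights = c(citalopram = 1,
                                                 sertraline = 1)),
               "at least 5")
  expect_error(generator_config(rng_seed = NA), "seed")
  expect_error(generator_config(mhs_delay_months_sd = 0), "delay")
})

test_that("every generated file parses with zero rejected rows", {
  gc <- generator_config(n_patients = 120L, rng_seed = 5L)
  out <- tempfile()
  generate_cohort(gc, dict, cfg, out_dir = out)
  rx <- suppressMessages(read_prescriptions(
    file.path(out, "prescriptions.csv"), dict, cfg))
  ev <- read_clinical_events(file.path(out, "events.csv"), dict)
  expect_equal(attr(rx, "n_rejected"), 0L)
  expect_equal(attr(ev, "n_rejected"), 0L)
  expect_true(all(rx$drug_role %in% c("antidepressant",
                                      "augmentation_agent")))
  expect_false(any(ev$category == "other"))
  ct <- read_contacts(file.path(out, "contacts.csv"))
  dm <- read_demographics(file.path(out, "demographics.csv"))
  expect_setequal(dm$patient_id, unique(rx$patient_id))
  # drug mix is dominated by the four headline drugs
  four <- c("citalopram", "sertraline", "fluoxetine", "mirtazapine")
  share <- mean(rx$ingredient[rx$drug_role == "antidepressant"] %in% four)
  expect_gt(share, 0.6)
})

test_that("classifier recovers generator labels exactly on a noise-free cohort", {
  gc <- generator_config(n_patients = 400L, rng_seed = 23L)
  out <- tempfile()
  syn <- generate_cohort(gc, dict, cfg, out_dir = out)
  rx <- read_prescriptions(file.path(out, "prescriptions.csv"), dict, cfg)
  ev <- read_clinical_events(file.path(out, "events.csv"), dict)
  ct <- read_contacts(file.path(out, "contacts.csv"))
  dm <- read_demographics(file.path(out, "demographics.csv"))
  coh <- build_cohort(rx, ev, dm, cfg)
  # eligibility matches truth, including the reason
  m <- merge(coh, syn$truth, by = "patient_id")
  expect_equal(m$eligible.x, m$eligible.y)
  bad <- m[!m$eligible.x, ]
  expect_true(all(mapply(grepl, bad$ineligible_type, bad$exclusion_reasons)))

  pw <- derive_pathways(rx, ev, ct, coh, dict, cfg)
  met <- compute_patient_metrics(pw, rx, ev, ct, coh, cfg)
  rec <- recover_parameters(syn$truth, pw$classifications, met, gc)
  expect_equal(attr(rec, "group_agreement"), 1)
  expect_equal(attr(rec, "lines_agreement"), 1)
  expect_equal(attr(rec, "script_count_agreement"), 1)
  # the confusion matrix is diagonal
  truth <- syn$truth[syn$truth$eligible, ]
  cls <- pw$classifications[match(truth$patient_id,
                                  pw$classifications$patient_id), ]
  expect_equal(unname(table(cls$group, truth$true_group)["MDD", "TRD"]), 0L)
  expect_equal(unname(table(cls$group, truth$true_group)["TRD", "MDD"]), 0L)
})

test_that("mismatched patient universes are refused", {
  gc <- generator_config(n_patients = 30L, rng_seed = 2L)
  syn <- generate_cohort(gc, dict, cfg)
  fake_cls <- data.frame(patient_id = "NOPE", group = "MDD",
                         n_responses = 0L, n_relapses = 0L,
                         lines_of_therapy = 1L, stringsAsFactors = FALSE)
  fake_met <- data.frame(patient_id = "NOPE", n_prescriptions = 0L,
                         stringsAsFactors = FALSE)
  expect_error(recover_parameters(syn$truth, fake_cls, fake_met, gc),
               "mismatched")
})
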