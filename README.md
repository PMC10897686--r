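# rxpathways

Derives depression care pathways and treatment-resistance status from raw
primary-care prescription records.

UK primary-care databases record antidepressant prescribing as one row per
issued script, with no explicit marker of treatment response, remission,
relapse, or resistance. `rxpathways` reconstructs those outcomes from the
prescribing record itself, for pharmacoepidemiologists and mental-health
services researchers who need patient-level treatment pathways from coded
EHR extracts — and, because such extracts are access-restricted, it ships a
label-first synthetic cohort generator so the entire rule set is testable on
any machine.

## The derivation

Scripts are expanded to half-open coverage intervals
`[issue_date, issue_date + supply_days)` (30-day default supply); gaps of at
most 60 days within one drug are bridged, and overlapping refills extend
coverage without stacking. The patient's timeline is then cut wherever the
set of concurrently covered antidepressants changes, giving maximal
constant-regimen **treatment sequences** — dose changes never cut a
sequence. Rules over sequences:

| outcome | rule |
|---|---|
| response | one sequence sustained ≥ 90 days (dose changes allowed) |
| remission | response ≥ 180 days, or a ≥ 90-day sequence followed by 60 antidepressant-free days |
| relapse | new sequence starting 60–180 days (inclusive) after a responding sequence ends |
| switch | ≥ 1 drug stopped and ≥ 1 introduced within the switch window |
| combination | regimen strictly enlarged and held ≥ 45 days |
| augmentation | lithium / antipsychotic / thyroxine / tri-iodothyronine / anticonvulsant overlapping a sequence ≥ 45 days |
| resumption | restart of a previously used regimen outside the relapse window |
| treatment failure | no response, or followed by a switch/combination, or augmented |

A patient is **TRD** (treatment-resistant depression) when one depressive
episode — a run of treatment not broken by remission or a > 180-day
treatment-free gap — contains at least two failed lines of adequate
duration (≥ 42 days) and dose, with differing regimens; otherwise **MDD**.
Lines are counted per episode from initiations (first start, switch,
combination); resumptions do not add lines.

Around the classifier sit cohort screening (adults with a depression code
and an antidepressant script in 2015–2020, no bipolar/dementia/mania/
psychosis/schizophrenia codes from 2010 on), per-patient and per-group
summary metrics, small-cell disclosure control (counts 0–4 render `"<5"`),
and the two group-comparison tests (Pearson χ² with 1 d.f.; Wilcoxon
rank-sum with continuity correction), implemented from first principles and
verified against independent references.

## Worked example

```r
library(rxpathways)

cfg  <- study_config()
dict <- default_code_dictionary()

# simulate a cohort with known labels, then run the pipeline on its files
gen <- generator_config(n_patients = 1000, rng_seed = 42)
dir <- tempfile()
syn <- generate_cohort(gen, dict, cfg, out_dir = dir)

rx <- read_prescriptions(file.path(dir, "prescriptions.csv"), dict, cfg)
ev <- read_clinical_events(file.path(dir, "events.csv"), dict)
ct <- read_contacts(file.path(dir, "contacts.csv"))
dm <- read_demographics(file.path(dir, "demographics.csv"))

cohort   <- build_cohort(rx, ev, dm, cfg)
pathways <- derive_pathways(rx, ev, ct, cohort, dict, cfg)
table(pathways$classifications$group)
#>  MDD  TRD
#>  873   83

metrics <- compute_patient_metrics(pathways, rx, ev, ct, cohort, cfg)
rec <- recover_parameters(syn$truth, pathways$classifications, metrics, gen)
attr(rec, "group_agreement")
#> [1] 1
rec[1, c("quantity", "configured", "estimated")]
#>         quantity configured  estimated
#> 1 trd_proportion       0.08 0.08682008
```

`873 + 83 = 956` of the 1000 simulated patients pass eligibility screening
(the generator plants ~5% rule violations to exercise the screen); every
eligible patient's MDD/TRD label and line count match the generator's
ground truth, and the estimated resistance proportion sits on the
configured 8%. A two-group comparison:

```r
m <- merge(metrics, pathways$classifications[, c("patient_id", "group")])
compare_groups(m, "remission_flag")
#> Pearson chi-square (df = 1)
#>   statistic = 9.37296, p = 0.002202
```

A thin command-line wrapper is installed at
`system.file("cli", "rx-pathways", package = "rxpathways")` with
`simulate`, `run` and `compare` subcommands.

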