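---
title: "Deriving depression treatment pathways from prescription records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving depression treatment pathways from prescription records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxpathways)
```

## The problem

Primary-care databases record antidepressant treatment as issued
prescriptions: a patient, a drug, a date, sometimes a dose and a supply
quantity. Nothing in the record says whether the patient responded,
remitted, relapsed, or cycled through failed treatments. Severity
instruments (PHQ-9 and relatives) are coded too sparsely to carry an
outcome analysis. `rxpathways` implements the alternative: *operational*
outcome definitions computed purely from prescribing dynamics, including an
operational definition of treatment-resistant depression (TRD) — no
response after at least two adequate, distinct oral antidepressant
treatments within a single depressive episode.

Every rule here is a modelling decision, not a clinical measurement. This
vignette records the model, the parameters, the choices that were genuinely
open, and what the accompanying tests do and do not establish.

## From scripts to sequences

All interval arithmetic is on calendar dates in integer days, and every
interval is half-open `[start, end)`; a 30-day script issued on day *d*
covers days *d* … *d*+29. A script with no recorded supply is imputed at
`default_supply_days` (30 days, the typical prescription length in this
setting).

**Coverage.** Within one patient and ingredient, script intervals are
merged when the gap between them is at most
`same_regimen_gap_tolerance_days` (60 days). Overlapping refills extend
coverage to the latest end; supply never stacks, because early refills are
routine and stacking would inflate exposure. Dose changes are recorded in a
dose trace and never split coverage.

**Sequences.** The patient's timeline is partitioned at every date where
the set of concurrently covered ingredients (the *regimen*) changes; each
maximal constant-regimen span is one treatment sequence. Because
same-ingredient gaps at or under the tolerance were already bridged, two
consecutive sequences either differ in regimen or are separated by more
than the tolerance. `dose_changes` per sequence counts distinct recorded
dose values per ingredient minus one; a missing dose is its own level
(missing equals missing, differs from any number).

The 60-day tolerance is the one load-bearing parameter the source
definitions never state. It is set equal to the remission look-forward
deliberately: a gap short enough that it does not signal remission also
should not fragment a sequence. It is configurable
(`study_config(same_regimen_gap_tolerance_days = ...)`), and a sensitivity
analysis on real data should vary it.

## Outcome rules

With durations in days and `gap` the distance from one sequence's end to
the next one's start:

* **Response** — duration ≥ 90. Dose changes are explicitly allowed;
  regimen constancy is guaranteed by construction.
* **Remission** — duration ≥ 180, *or* duration ≥ 90 with no
  antidepressant coverage beginning in the 60 days after the sequence ends.
  The look-forward window is half-open: a restart exactly 60 days after the
  end does not block remission. The gap clause is evaluated only when the
  full 60-day window is observable before the study end; otherwise a
  patient still on treatment at the censoring boundary would count as
  remitted by discontinuation.
* **Relapse** — a new sequence starting 60–180 days (both endpoints
  inclusive; the source range is ambiguous and this reading is
  configurable) after the end of a responding sequence.
* **Switch** — at least one drug stopped and at least one introduced. The
  source frames its 60–180-day window as tolerance for prescribing delays;
  by default this package also classifies immediate replacements
  (gap < 60 days, including same-day) as switches, since a replacement
  with no gap is unambiguously a switch. `switch_gap_min_days = 60`
  restores the literal windowed behaviour.
* **Combination** — the regimen strictly enlarged and the enlarged regimen
  held ≥ 45 days.
* **Augmentation** — lithium, an antipsychotic, thyroxine,
  tri-iodothyronine or an anticonvulsant whose merged coverage overlaps a
  sequence by ≥ 45 days; an agent spanning two sequences long enough
  attaches to both.
* **Resumption** — restart of a previously used regimen outside the
  relapse window (an undefined term in the source beyond its tabulation;
  this is the package's reading).
* **Treatment failure** — a sequence with no response, or followed within
  its episode by a switch or combination, or with an augmentation
  attached. Note the consequence: a responding sequence that is then
  switched away from or augmented still counts as a failed line.

When several transition rules fire on one boundary the precedence is
combination > switch > resumption: a strict superset regimen is more
specific than a replacement, and both are more informative than a repeat.

Two interactions are worth knowing. First, a relapse after a response
implies the responding sequence had ≥ 60 drug-free days, so remission (by
discontinuation) and relapse regularly co-occur on one pathway — remit,
then relapse — exactly as the definitions compose. Second, a same-drug
restart at a gap of exactly 60 days cannot exist as a separate sequence
(the merge tolerance bridges it), so a relapse at exactly 60 days requires
a regimen change; same-drug relapses occur at gaps of 61–180 days.

## Episodes, lines, and the TRD rule

An **episode** closes at a remission or at a treatment-free gap strictly
greater than 180 days. (The source's episode note says "no prescription
within 180 days", while its relapse window is inclusive at 180; closing at
> 180 keeps a relapse at exactly 180 inside its episode, resolving the
single-point conflict in favour of the relapse definition.)

A **line** is a distinct regimen initiated by an episode's first sequence,
a switch, or a combination; resumptions never add lines. A patient's
`lines_of_therapy` is the maximum line count reached within any single
episode.

**TRD** requires, within one episode, at least two failed lines with
differing regimens, each adequate. Only line-initiating sequences are
eligible — otherwise a sub-45-day drug addition (too short to be a
combination) would contribute a failed "line" and produce a TRD patient
with one line of therapy, which the invariant TRD ⇒ lines ≥ 2 forbids.
Adequacy is duration ≥ `adequate_line_min_days` (42 days: the source says
only "adequate dose and duration", and national guidance reviews treatment
at 4–6 weeks), plus dose adequacy enforced exactly when both a recorded
dose and a dictionary minimum effective dose exist. Both are configurable.

## Cohort screening and metrics

Eligibility: an index date (first antidepressant script in 2015–2020), age
≥ 18 at index (a missing date of birth makes adulthood unresolvable and the
patient ineligible, flagged), a depression code at any time up to the study
end (codes recorded after the first script still qualify), and no
bipolar/dementia/mania/psychosis/schizophrenia/schizoaffective code from
2010 onwards. Sequence building uses only scripts issued inside the study
window, and coverage is censored at the day after the study end.

Day-to-month conversions use 30.44 days/month throughout. Duration of
depression runs from the earliest depression code to the first response
(dated `sequence start + 90` days) or the study end; time in study runs
from index to study end (not to last record — the source is ambiguous).
Time to first secondary-care mental-health contact runs from the earliest
depression code to the earliest of a referral code or any recorded service
contact (A&E, crisis, liaison, community and inpatient routes count without
a referral). A contact predating the first depression code yields a
negative duration kept with a warning: it is a data-quality signal, not a
value to clip.

Aggregate tables pass through small-cell suppression: every integer count
from 0 to 4 renders as the string `"<5"`, totally and idempotently.

## The two tests

Group comparisons use a first-principles Pearson χ² on 2×2 tables
(1 d.f., no continuity correction by default — the source names none;
Yates' correction is a flag) and a Wilcoxon rank-sum with midranks,
tie-corrected variance, a 0.5 continuity correction, and a normal
approximation regardless of sample size, appropriate for cohorts of this
scale; exact enumeration is available for ≤ 10 per group as a verification
path. Both are checked against R's reference implementations to 1e-8 on a
frozen fixture file and on fresh random fixtures, and the Wilcoxon's
type-I error is simulated at α = 0.05 over 2000 null replicates.

## The synthetic cohort generator

Real extracts of this kind are access-restricted, so the generator is a
first-class module, not a fixture. It writes trajectories *label-first*:
each patient is assigned a group and a path template whose classifier
outcome is provable from the rules above, then the template is rendered
into ~30-day scripts with adherence gaps drawn from a short/long mixture
(0–10 days mostly, occasionally 25–55 — always under the merge tolerance,
so gaps exercise interval stitching without breaking sequences).

Defaults emulate the study conditions: 8% of eligible patients destined
for TRD; citalopram, sertraline, fluoxetine and mirtazapine carrying 83%
of prescribing mass; response probability 0.30 for MDD patients and 0.13
for the TRD group's post-failure line (which, in these templates, also
fixes the TRD remission rate, since every simulated responder remits by
duration or discontinuation); relapse probability 0.30/0.50 given
response; TRD failed-line counts of 2/3/4 with weights 0.67/0.24/0.09;
comorbidity, suicidality and secondary-care contact rates higher in the
TRD group; a gamma-distributed contact delay with a 40-month mean; and a
5% planted-ineligible fraction (minors, exclusion codes, missing
depression codes, pre-window-only prescribing) to exercise the screen.
These were chosen once as the simulation conditions and are not tuned.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: coding errors and true missingness; chronic
high-volume prescribing (templates are minimal label-realizing paths, so
scripts per patient run well below real-world counts and the TRD/MDD
volume ratio is compressed); contact delays right-truncated at the study
end (realized mean ≈ 33 months against the configured 40); calendar
structure (dates are uniform, no weekends or holidays); and any regimen
dynamics outside the template vocabulary. Recovery tests establish that
the classifier inverts the generator exactly and that estimated rates sit
within three standard errors of configured ones — they are consistency
checks on the rule implementations, not validation against clinical truth.

## Numerical and degenerate-input choices

* Dates parse strictly as ISO `YYYY-MM-DD`; impossible dates reject the
  row with a diagnostic rather than guessing.
* Overlapping sequences passed to the transition classifier are a
  construction bug and raise a hard error.
* A 2×2 table with a zero margin is degenerate and errors; an all-tied
  Wilcoxon has zero variance and returns p = 1.
* Empty groups in summary tables yield suppressed/NA rows, never division
  by zero.
* The pipeline is a pure function of (inputs, configuration, seed): reruns
  are byte-identical, asserted by checksum in the manifest.

## Problem sizes used by the test suite

The suite exercises 21 hand-built boundary archetypes; 500 random patients
against a day-by-day sequence oracle and an exhaustive pairwise
rule oracle; a 5000-patient label-recovery cohort; 2000 null replicates
for test size; and full-pipeline determinism on ~100-patient runs. These
sizes were chosen to give exact oracle coverage and ~3-standard-error
statistical bands at desk scale.

## Known limitations

The operational definitions inherit the source's blind spots: patients
parked on an ineffective drug never meet the failure-by-change clauses
beyond non-response; psychological therapy and specialist treatments
(e.g. electroconvulsive therapy) are invisible to prescribing data;
dispensing and consumption are assumed to follow issuance. The response
and failure definitions are not mutually exclusive (a > 90-day sequence
followed by a switch is both), and both tallies are emitted so either
reading of the source's tables can be reproduced. None of the outputs
support causal interpretation.
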