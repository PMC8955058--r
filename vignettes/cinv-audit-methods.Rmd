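---
title: "Auditing chemotherapy emetic risk and antiemetic prophylaxis in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing chemotherapy emetic risk and antiemetic prophylaxis in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinvaudit)
library(dplyr)
```

## The problem

Chemotherapy-induced nausea and vomiting (CINV) is one of the adverse events
patients fear most, and its expected severity is largely determined by the
emetogenic potential of the regimen. Clinical guidelines (JSCO, ASCO, NCCN,
MASCC/ESMO) grade agents into high / moderate / low / minimal emetic-risk
categories and recommend prophylaxis accordingly: a three-drug combination
(an NK1 receptor antagonist, a serotonin receptor antagonist, and
dexamethasone) for high-risk chemotherapy, a two-drug combination for
moderate risk, and so on.

`cinvaudit` implements a reproducible audit of this practice in linked
cancer-registry and administrative-claims data: it selects a first-course
chemotherapy cohort, assembles each patient's first 8 days of chemotherapy
into one combination regimen, classifies the regimen's emetic risk from
packaged rule tables, attributes antiemetic claims to the course as
prophylactic using timing windows, and tabulates stratified proportions with
exact binomial confidence intervals. Because registry-linked claims data are
not publicly shareable, the package also ships a synthetic generator that
emulates such data with known ground truth, so that every stage of the
pipeline is testable end to end.

## Cohort construction

Patients enter the cohort if they are at least 20 years old at diagnosis (in
the configured diagnosis year) and receive chemotherapy on or after the
diagnosis date. The *first course* starts at the earliest chemotherapy
administration and spans 8 inclusive calendar days; everything administered
in that window is treated as one combination regimen. The inclusive-window
convention is forced by a common gastric-cancer pattern in which cisplatin
is added on day 8 of an S-1 course: day 8 must fall inside the regimen.
Calendar days, not days-with-administration, are counted; dates have
day resolution.

Exclusions, each evaluated against the course window:

* interferon-alpha in the course (used for non-oncological indications);
* chemotherapy on the same day as surgery or thoracic/abdominal/pericardial
  drainage (the drug may have been administered topically);
* any arterial-route administration;
* haematopoietic stem cell transplantation within 21 days *after* a course
  administration (conditioning chemotherapy precedes transplant; a symmetric
  window is available via `audit_config(hsct_symmetric = TRUE)`);
* age under 20 at diagnosis.

A flow log counts patients at every step, and the partition invariant
`input N = retained N + unique excluded N` is enforced by test. A patient
with several reasons is counted once, with all reasons logged.

Courses containing any intravenous drug form the intravenous group; courses
of exclusively oral drugs form the oral group. Mixed regimens such as S-1
plus cisplatin go to the intravenous group because their emetogenic driver
is the IV component; the source material never defines this split, so it is
a documented package assumption. The combined disease stage is the
pathological stage for resected patients when available, otherwise the
clinical stage.

## Risk classification

Rule tables are shipped as versioned CSV files, one per guideline system,
with single-agent rows and (for JSCO) named combination overrides. Key
numeric conventions:

* **Dose per body surface area.** Claims record absolute mg; guideline tiers
  are written in mg/m2. Patient-level BSA is unavailable in claims, so a
  population-average 1.48 m2 (average Japanese adult) is assumed
  (`audit_config(bsa_m2 = ...)` to change). Two NCCN anthracycline
  thresholds are written in absolute mg and are encoded as such
  (`bound_unit = "mg"`).
* **Tier boundaries** follow the stated inequalities literally:
  methotrexate <50 / 50-250 / >250 mg/m2 maps to low / moderate / high with
  a *closed* middle interval (50 and 250 both resolve to moderate);
  cyclophosphamide >1500 mg/m2 is high, so exactly 1500 is moderate;
  cytarabine >200 mg/m2 (JSCO, NCCN) or >1000 mg/m2 (ASCO, MASCC) is
  moderate, the boundary itself low.
* **Missing dose** on a dose-tiered drug resolves to the drug's middle
  (most common clinical) tier with a warning - claims frequently omit doses,
  and the middle tier is the least-bad default; `missing_dose = "unknown"`
  opts out.
* **Carboplatin under NCCN** is graded by AUC, which cannot be recovered
  from a mg dose without renal function; an explicit `auc` argument resolves
  the tier, otherwise carboplatin is moderate with a warning.
* Blank cells in the four-system comparison (MASCC nelarabine and
  pertuzumab) are encoded as `unknown` rather than inferred.

A regimen's category is the firing combination override if any, else the
**maximum** single-agent category over its components (unknown components
are ignored; an all-unknown regimen is unknown). The maximum rule is a
package design decision: the source material never states the aggregation
explicitly, but the maximum is the only rule consistent with its published
regimen placements (carboplatin + paclitaxel moderate, S-1 + cisplatin high)
and with guideline practice. Combination overrides - FOLFOXIRI (colorectal),
FOLFIRINOX (pancreatic), GS and gemcitabine + nab-paclitaxel (pancreatic),
ICE (lymphoma), oral etoposide / nimustine / ranimustine (lymphoma), and
anthracycline + cyclophosphamide - match by *subset*, so rituximab plus CHOP
still fires the anthracycline override, and are tried most-specific first
(more components, then context-restricted, then lexicographic name as a
deterministic tie-break). Supportive steroids inside a regimen (CHOP's
prednisolone) are steroid-class claims and never enter the chemotherapy
component set.

```{r}
classify_single_agent("methotrexate", 59.2, "IV")  # 40 mg/m2 at 1.48 m2
compare_guidelines("cetuximab")
```

## Prophylaxis attribution

An antiemetic claim is attributed to the course as prophylactic when

(a) it is dated on the course start date (any route); or
(b) a course component whose single-agent category is *high* is first
    administered after the start date and the claim shares that
    administration date (the S-1 day 1 / cisplatin day 8 pattern); or
(c) it is an oral prescription dated within the 30 days before the start,
    inclusive of day -30 (oral antiemetics are often dispensed in advance).

Rule (b) is keyed to the high-risk component's administration date, not to
all later days, and applies to high-risk components only by default - the
analogous escalation for moderate-risk drugs is not documented practice, so
it sits behind `audit_config(escalation_categories = ...)`. Rule (c) is
deliberately oral-only. Attributed classes collapse to five mutually
exclusive categories: triple (all three classes, any systemic corticosteroid
counting as the steroid), serotonin antagonist + dexamethasone, serotonin
antagonist alone, dexamethasone alone, none. An NK1 antagonist without both
partners matches no published category; such profiles fall through to the
category of their serotonin/steroid pair and are counted in a dedicated
`nk1_unpartnered` audit column, keeping the five-way partition exact while
making the ambiguity measurable.

## Proportions and intervals

All proportions are computed at full precision on explicit denominators
(category percentages include the unknown category in the denominator,
matching the published convention) and presented half-up at one decimal.
The default interval is the exact Clopper-Pearson interval via beta
quantiles - the default of the statistical software named by the source
analysis - with the Wilson score interval available by configuration. Tests
verify the endpoints against an independent numerical inversion of the
binomial CDF and check simulated coverage at n = 500, p = 0.7 (the exact
method is conservative, so coverage is at least nominal).

`expected_vomiting_frequency(p, with, without)` implements the mixture
arithmetic `p * with + (1 - p) * without` used to communicate the expected
population vomiting frequency under partial prophylaxis coverage: with 90%
coverage, 30% vomiting under prophylaxis and 90% without, the mixture gives
0.36.

## The synthetic generator

`generate_dataset()` draws, per patient: a cancer type from the published
cohort composition; a risk cell from a per-cancer split; a named regimen
from the published within-cell shares (renormalised); demographics, stages
and dates; the regimen's component administrations at its day offsets; and
a prophylaxis category from the published per-stratum prescription rates
(route group x risk category, renormalised from one-decimal percentages),
realised as antiemetic claims on the attribution-relevant date. A
configurable fraction of patients receives its prophylaxis as oral
prescriptions inside the 30-day lookback, exercising rule (c); the S-1 +
cisplatin regimen places prophylaxis on day 8, exercising rule (b);
`timing_noise` displaces a patient's antiemetic claims outside every
attribution window. Exclusion-triggering noise injects at most one
construct per patient (interferon-alpha line, same-day surgery, arterial
line, transplant at day +14, under-20 age, or removal of all claims).

Ground truth is *consistent with the emitted claims by construction*: for
regimens that themselves contain a systemic steroid on the attribution date
(CHOP's prednisolone), the recorded true prophylaxis category is derived
after adding that steroid, so a sampled "none" is truthfully recorded as
"dexamethasone only". `implied_marginals()` computes the population
frequencies a pipeline run should recover, accounting for this mapping and
for timing noise; recovery is tested at n = 20,000 within three binomial
standard errors, and per-patient agreement is tested to be exact with noise
and exclusions off. Nothing in the pipeline reads the truth channel.

Values not printed in the source material were fixed once at plausible
levels and not tuned: the non-small-cell-lung and "other" risk splits, the
within-cell shares of unlisted regimens, component doses (chosen at typical
body-surface-adjusted levels for a 1.48 m2 adult), the 30% oral-lookback
fraction, and the default exclusion-noise rates (0.2-0.4% per reason). The
pancreatic minimal-risk cell is empty in the published regimen table, so
its residual mass sits in the low-risk cell.

What the generator does *not* emulate - and hence what passing tests do not
show about real data: real billing-code vocabularies and their mapping
noise, dose recording errors, multi-course trajectories, within-hospital
correlation, therapeutic (as opposed to prophylactic) antiemetic use beyond
the timing windows, and patient-level CINV risk factors.

## Problem sizes and runtime choices

The test suite runs the full generator-to-tables recovery at n = 20,000
patients and the interval coverage simulation at 1,000 replicates of
n = 500; both finish in seconds and were chosen as the smallest sizes at
which three-standard-error recovery bounds are meaningfully tight. The
packaged 30-patient fixture is small enough to verify by hand and covers
every exclusion reason, the day-8 escalation case, an oral-only patient,
both oral-lookback boundaries, and an unpartnered-NK1 profile.

## Known limitations

* Attribution is timing-based only; therapeutic same-day use is
  indistinguishable from prophylaxis in claims.
* The packaged rule tables cover the drugs of the published comparison and
  regimen tables, not any guideline's complete catalogue; users may extend
  the CSVs (`load_guideline_table(agents_file = ...)`).
* Dose-per-BSA classification with a population-average BSA misclassifies
  patients far from 1.48 m2 for dose-tiered drugs.
* Olanzapine-era (post-2016) prophylaxis categories and radiotherapy
  emetogenicity are out of scope.
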