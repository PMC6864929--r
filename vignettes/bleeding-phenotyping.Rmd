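---
title: "Phenotyping bleeding events in linked electronic health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping bleeding events in linked electronic health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bleeding is among the commonest serious harms of antithrombotic therapy,
but routine health data record it piecemeal: a general-practice code here, a
hospital discharge diagnosis there, sometimes only a transfusion or a
falling haemoglobin, and for the most severe events a cause of death. No
single source is complete, and events recorded in several sources must not
be double-counted. `bleedpheno` implements a rule-based phenotyping
algorithm that assembles bleeding evidence across three linked sources —
primary care, hospital admissions and a death registry — and classifies
each event by severity, together with the exposure and survival machinery
needed to study bleeding risk under antithrombotic therapy.

## The phenotyping algorithm

**Record assembly.** Every coded bleeding diagnosis becomes one record:
primary-care events dated at the consultation; hospital diagnoses dated at
admission, carrying the diagnosis position (1 = primary reason for
admission) and the length of stay (discharge minus admission, in days);
death-registry causes (underlying or contributory) dated at death. Codes
are classified through a codelist in which every bleeding entry carries an
anatomical site. ICD-10 and OPCS-4 codes are normalised (dots removed,
upper-cased) and matched exactly first, then by the longest listed prefix
of at least three characters — hospital extracts mix dotted and undotted
forms, and ICD lists are commonly maintained at the three-character block
level. Read-like primary-care codes are matched verbatim.

**Event grouping.** Records of one patient no more than 30 days apart (single
linkage) form one event, dated at the earliest record. Thirty days is the
standard window for linking one clinical episode across sources; we adopt
it as the single event definition everywhere, and it is configurable.
Grouping is a partition: permuting the input rows never
changes the result, a property the test suite checks against a union-find
oracle.

**Fatal bleeding.** An event is fatal if it contains a bleeding cause of
death, or if all-cause death occurs within 0–7 days (inclusive) after a
primary-care or hospital bleeding record. Deaths before the record never
count. A death-registry bleeding cause with no nearby records still forms
its own fatal event dated at death (`include_death_only = FALSE` drops
these).

**Markers of severity (MS).** Four record-level features upgrade a
non-fatal event:

1. bleeding as the primary hospital diagnosis with at least 14 days of
   hospitalisation (satisfied at exactly 14);
2. a critical site — intracranial, ruptured aortic aneurysm, or
   haemopericardium;
3. bleeding from two or more distinct anatomical sites on the same day
   (two codes for the same site are one site);
4. a hospital transfusion within ±30 days of a bleeding record. The window
   is symmetric by default because transfusions commonly precede the coding
   date within one admission; a forward-only variant is a flag.

**Categories and prognostic classes.** Precedence: fatal >
hospitalised+MS > primary-care+MS > hospitalised > primary care. An event
with any hospital record is "hospitalised"; a tie between hospitalised+MS
and primary-care+MS cannot occur because hospital presence decides.
Categories map to prognostic classes: hospitalised+MS = I; hospitalised,
primary-care+MS and inferred = II; primary care without markers = III.

**Inferred bleeding.** For patients with *no* coded bleeding diagnosis in
primary care or hospital records, indirect evidence is scanned through
four routes, in order: (1) transfusion plus an iron-deficiency-anaemia
diagnosis within 30 days of each other; (2) a surgical procedure to arrest
bleeding or evacuate a haematoma; (3) haemoglobin below 10 g/dL plus
anaemia plus endoscopy within one 30-day span; (4) transfusion plus low
haemoglobin plus endoscopy within one span. Routes 3 and 4 require no
cancer, liver-disease or renal-disease record in the 365 days ending the
day before the anchor (the earliest component date) — those conditions
explain the same signs without bleeding. One evidence span yields one
event (the first matching route wins). Two genuinely open readings were
settled as follows: the route-3 haemoglobin must itself fall inside the
30-day span (the stricter reading; `require_hb_in_span = FALSE` allows it
up to 90 days before the anchor), and the exclusion lookback ends the day
before the anchor because a same-day diagnosis is more plausibly a
consequence of the bleed than a competing explanation.

## The antithrombotic exposure model

Prescription issues of three classes (aspirin, ADP-receptor inhibitors,
vitamin K antagonists) are merged into episodes when consecutive issues
are at most 90 days apart — the longest allowed UK prescription duration —
and an episode covers 90 days beyond its last issue, the same figure read
as per-issue coverage; both are configurable. Overlaying the three classes
tiles each patient's follow-up with seven states: none (reference),
aspirin monotherapy, ADP-inhibitor monotherapy, dual antiplatelet therapy,
VKA monotherapy, VKA plus one antiplatelet, and triple therapy. All
intervals are half-open `[start, end)` in whole days, so durations are
unambiguous differences. VKA with two antiplatelets is the single `triple`
state. Duration summaries report medians and interquartile ranges over
patients ever exposed to a state, with type-7 (linear-interpolation)
quantiles, stated because the choice of quantile rule is otherwise
invisible.

## Cohort and survival analyses

Patients enter at their first AF, MI, unstable- or stable-angina diagnosis
in primary-care or hospital records, aged 18 or over; same-day
multi-disease ties are broken mi > ua > af > sa (a documented convention —
the acuter condition wins). Follow-up ends at death, transfer out of the
practice, or administrative censoring (default 2010-03-31). Baseline
comorbidity flags use any record strictly before entry; baseline
biomarkers take the record nearest to entry within the half-open year
`[entry − 365, entry)` — "prior to entry" excludes the entry day.

Incidence uses the Kaplan-Meier estimator (Greenwood variance, log-log
intervals) reported as cumulative incidence 1 − S(t). Monthly rates divide
events in a calendar month by patients whose follow-up overlaps any day of
that month (a patient present for one day counts; the alternative
"alive at month start" is a flag), per 1000, with a normal approximation
to the Poisson count and the lower bound clamped at zero; loess (tricube,
locally linear, span 0.75 by default — a smoothing choice, stated because
no single span is canonical) smooths the series.

Both therapy state and bleeding-severity state enter Cox models as
time-dependent covariates in counting-process form: follow-up is split at
every state change, so person-time before a state is attained is never
attributed to it. This is what prevents immortal time bias, and the test
suite demonstrates the bias by refitting the same data with exposure fixed
at baseline ("ever exposed"): the planted hazard ratios are then missed
badly. For prognosis, every patient starts in `no_bleed` and moves to the
class of their first event at its date, where they remain — the data
describe only the first transition, so later class changes are out of
scope. Models adjust for age (linear in years — the functional form is a
modelling choice) and sex, prognosis models additionally for eight baseline
comorbidities. Ties use the Efron approximation (Breslow by flag);
convergence is Newton-Raphson inside `survival::coxph` with a tightened
tolerance (`eps = 1e-9`, 50 iterations); zero-variance covariates are
rejected before fitting and suspected separation is flagged from the
fitter's own warnings. An outcome on the entry day is counted at half a
day so its row has positive length. Proportional hazards are checked with
Schoenfeld-residual trend tests and log(−log) survival curves. Diagnostic
accuracy (PPV, NPV, sensitivity, specificity) uses exact Clopper-Pearson
intervals. Recurrent bleeding restarts the clock at the first non-fatal
event, stratified by whether that event carried markers of severity.

## The synthetic linked-EHR generator

Real linked EHR (CPRD/HES/ONS-style) are licensed and cannot ship with a
package, so every stage is exercised on a simulator whose ground truth is
known. `sim_config()` defaults describe the study conditions the package
targets: entry 1997–2010, mean age 71.5 (SD 13), 48.5% female, index-disease
mix 21/19/7/52% across AF/MI/UA/SA, a baseline bleeding hazard of
1.4 × 10⁻⁴ per day (about one patient in four bleeding within five years),
therapy hazard ratios rising from 1.3 (aspirin) through 2.0 (dual therapy)
to 3.4 (triple), post-bleed mortality multipliers 3.0/2.0/1.2 for classes
I/II/III, and capture probabilities under which roughly 59% of bleeds gain
a primary-care code, 50% a hospital bleeding code (0.707 attendance × 0.71
coding — the split lets validation samples contain attended-but-uncoded
bleeds), and 3.8% a bleeding cause of death (which is also the fatal-bleed
mechanism). Four percent of bleeds leave only indirect evidence,
distributed over the four inference routes 46/32/17/5% — transfusion-plus-
anaemia being the commonest evidence pattern and the full
transfusion/haemoglobin/endoscopy combination the rarest.

Event times are piecewise exponential: the bleeding hazard multiplies the
baseline by the hazard ratio of the current therapy state (with competing
exponential clocks redrawn at each state change, the continuous-time
equivalent of a piecewise-constant-hazard Cox model), and mortality and
atherothrombotic hazards are multiplied from the first bleed onwards by
class-specific ratios. Prescription issue streams are emitted with
inter-issue gaps well under 90 days and episode ends defined as last issue
plus 90, so the analysis-side gap rule reconstructs the generating exposure
exactly — by design, since the generator's exposure *is* defined through
prescription coverage. Successive bleeds of one patient are at least 31
days apart, so one true bleed maps to one 30-day-grouped event and
perfect-capture configurations give exact round trips (sensitivity and PPV
of 1, matching dates), which the acceptance tests verify at n = 5000.

The generator is fully vectorised and driven by one global seed: the same
seed and configuration reproduce the tables byte for byte. (A splittable
per-patient stream — per-patient output invariant to cohort size — was
considered and set aside; seed-level determinism is the property the tests
rely on, and vectorised generation is an order of magnitude faster in R.)

What the simulator does *not* emulate, and what passing tests therefore do
not show about real data: realistic UK coding frequencies and code-choice
idiosyncrasies; secular trends in prescribing and coding (the synthetic
world is stationary, so monthly-rate series are flat apart from noise);
free text; correlated capture across sources (captures are independent
Bernoulli draws, so multi-source overlap is higher than the ~13% seen in
real linked data); ICD-9 death coding; and in-hospital or over-the-counter
drug exposure. Results on synthetic data validate the *machinery* — rule
boundaries, grouping, exposure construction, estimator calibration — not
the clinical performance of any particular codelist.

## Numerical and scale choices

Validation studies in the test suite and the acceptance script use problem
sizes chosen to give stable estimates on a single CPU: n = 5000 for the
round trip, n = 10,000 for the closed-form Kaplan-Meier check, 50
replicates of n = 20,000 for hazard-ratio coverage (planted ratios 2.0 and
5.7; both 95% CIs cover in ≥ 90% of replicates, while the naive
ever-exposed refit covers in far fewer), 1000 random episode sets against
a day-resolution exposure oracle, and 100 random confusion matrices
against exact-binomial formulas. The bundled codelist is illustrative: it
covers every category and site the rules consult, in the same schema as a
production terminology list, but it is not a clinically curated list and
ships as data a user is expected to replace.

## Known limitations

- Site classification assumes one site per code; codes meaning "multiple
  sites" are not modelled.
- The inference routes treat hospital procedure dates as recorded; where
  only an admission date exists upstream, route windows inherit that
  coarseness.
- Monthly denominators count patients whose follow-up overlaps the month;
  with very short registration gaps this can differ from an
  "active patient" register kept by a practice system.
- Cox models use age at entry; age is not updated during follow-up (the
  time scale is time since entry, and cohort effects are absorbed by the
  linear term only approximately).
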