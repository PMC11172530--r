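---
title: "Simulating an SOP-derived melanoma pathway and scoring its data completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an SOP-derived melanoma pathway and scoring its data completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melpathsim)
```

## The problem

Hospital standard operating procedures (SOPs) for melanoma prescribe, step
by step, how a stage III patient with an indication for sentinel lymph node
excision (SLNE) should be worked up, treated adjuvantly and followed up.
Turning such a textual SOP into an executable clinical algorithm raises two
questions this package addresses:

1. **Simulation**: can a patient's electronic health record, represented as
   a FHIR-style resource bundle, be walked through the algorithm end to
   end — and where does missing data stop the walk?
2. **Completeness**: are the parameters the algorithm consumes at a
   decision point the same ones clinicians say they need there at the
   point of care?

The package models the pathway as a typed decision graph with 27 decision
points, simulates whole cohorts through it with full execution tracing, and
implements the survey-based completeness and concordance statistics.

## The patient model

A patient is a bundle of typed resources (demographics, conditions,
observations, procedures, diagnostic reports, episodes of care), one JSON
file per patient. Sixteen clinical parameters drive the decision points:
age at primary diagnosis (years), sex, date of first diagnosis, Breslow
tumor thickness (mm), ulceration status, resection status (R0/R1), mitotic
rate (per mm²), melanoma setting, pT category, lymph node sonography
findings, clinical and radiological metastasis detection, AJCC tumor
stage, BRAF status, SLNE status, and capsular breakthrough.

Extraction is driven by a rule table (parameter → resource kind + code +
value type) shipped as `extdata/default_mapping.json`. The original SOP's
query catalogue is not public, so this mapping is a reconstruction by
parameter name; it is configuration, not code, and can be revised without
touching the engine. Three rules matter:

* **Tri-state availability.** Every parameter is `present`, `unknown`
  (a resource exists but carries no value) or `absent` (no resource).
  Missing data is a first-class state, never silently imputed. Note that
  ulceration *"unknown"* is a recorded coded value (present) — it is what a
  pathologist reports when there is no primary tumor to assess — and is
  distinct from a missing ulceration record.
* **Recency.** When several dated candidates exist, the most recent
  effective date wins. Two candidates with the same date and conflicting
  values raise an ambiguity error attributed to the patient: silent
  tie-breaking would hide exactly the data-quality faults the analysis is
  about.
* **Age derivation.** Age at primary diagnosis is read directly when
  recorded, otherwise derived as whole completed years between the birth
  date and the date of first diagnosis. All dates are ISO 8601 calendar
  dates; the pathway has no time-of-day semantics.

## The pathway graph

The graph is a JSON document (`extdata/default_graph.json`) of typed
nodes: one start node, task nodes, decision nodes (gateways), an
individualized-treatment checkpoint, and end events that are either
*regular* or *preliminary* (an early exit for patients whose treatment
leaves the standardized pathway). The shipped default has exactly 27
decision points. Its topology is a documented reconstruction: the source
material publishes the decision-point questions, their logical order, and
an abstract flowchart, but not the full branch logic, so the connecting
structure — and in particular the tumor-conference block (DP16–DP21), the
DP8 risk-factor set (ulceration, thickness ≥ 0.75 mm, elevated mitotic
rate ≥ 1/mm²) and the constant MRI-compatibility answer at DP10 (MRI
compatibility is not among the 16 parameters) — reflects this package's
reading of standard melanoma practice and is meant to be edited in the
config, not trusted as the hospital's exact logic.

Decision predicates are written in a small condition language: leaves
compare one parameter (`eq`, `gt`, `in`, AJCC-ordered `stage_ge`,
follow-up-year operators, ...) and combine under `all`/`any`/`not`.
Evaluation is **Kleene three-valued** with the rules tried in declared
order: a rule whose condition is decidably true selects its branch; a
condition that cannot be decided because a needed parameter is unavailable
yields the missing-data outcome naming the parameters. The engine never
guesses, but it also never demands data it does not need — a patient with
pT = T0 (melanoma of unknown primary, MUP) is routed down the MUP branch
at DP1 before tumor thickness is ever consulted, which is what lets a
13-patient MUP sub-cohort without primary-tumor findings traverse the
graph. Every single-select decision must end in an always-true catch-all
rule, checked at load time, so evaluation is total.

Two decision points are structurally present but not exercised by default
cohorts: DP6 (R1 re-resection; the cohort is all-R0 by inclusion
criterion) and DP22 (tumor-conference decision after side effects, reached
only through a branch the default predicates never select, resolving to a
preliminary end). The MRI-compatibility gateway exists as two node
instances sharing one decision-point tag — it is consulted before the
sentinel excision and again before adjuvant therapy — so pass counts at
that tag count visits, not patients.

Graph validation collects *all* violations at once: duplicate ids,
dangling branches, unreachable nodes, predicates referencing undeclared
parameters (so an evaluation-time configuration error is impossible by
construction), missing catch-alls, and illegal cycles. The only legal
cycle is an explicitly marked follow-up loop edge guarded by a
year-bound predicate; traversing it advances the simulated follow-up year
by one, so it terminates by construction. The shipped default graph is
acyclic: the study design evaluates each patient once at a fixed reference
date (2023-10-26 by default) rather than projecting future follow-up
years, and the published per-decision-point counts are only consistent
with that single-pass reading. The loop machinery is retained and tested
on a toy graph for configurations that do want year projection.

Follow-up year convention: year *n* begins on the (*n*−1)-th anniversary
of first diagnosis, so the day of the 5th anniversary already starts year
6. This makes the "sixth follow-up year or higher" and "sixth to 10th
year" boundaries well-defined; the source states no rule, so the
convention is this package's choice, applied consistently.

## The simulation engine

`traverse()` walks one patient and records every step as a table row:
tasks, gateways, one `parameters-used` row per declared parameter at each
gateway (the audit snapshot: name, value, availability), the chosen
outgoing sequence(s), and the end event. Multi-select gateways (DP16, the
tumor-conference resolution) may select several branches; each selected
branch's task is recorded in declared order before the flow continues at
the gateway's join node — flowcharts of this kind have no parallel
execution semantics, so the order is documentation, not concurrency.
Missing data aborts at the gateway (terminal status
`aborted-missing-data`); where the gateway declares a missing-data branch
(DP1's "cannot determine" option) the trace exits through it to its
preliminary end. Twelve patients per default cohort carry an
individualized-treatment flag honored at a checkpoint before DP16; the
source does not publish how those patients were identified, so the flag is
explicit rather than inferred.

`simulate_cohort()` processes patients in id order (the output is
invariant under permutation of the input), collects per-patient extraction
errors without stopping the run, and maintains pass counts incrementally.
`summarize_traces()` recomputes the same summary independently from the
trace table, and the test suite asserts the two routes agree. Flow
conservation — visits into each single-select gateway equal branch outflow
plus in-place aborts — is asserted on every pipeline run. Traces export to
an RFC-4180 CSV with a stable column order that is byte-identical across
runs; a hand-walked golden trace is committed and compared byte-for-byte.

## The synthetic cohort

The real cohort is restricted, so the generator builds a synthetic twin of
the published baseline table: n = 67; sex 24 female / 43 male; stage IIIA
2, IIIB 28, IIIC 35, IIID 2; BRAF 29 mutation / 37 wildtype / 1 unknown;
pT leaves T0 13, T1a 4, T1b 1, T2a 6, T2b 4, T3a 10, T3b 10, T4a 6, T4b
13 (the published T1–T4 rows are subtotals of their a/b sub-rows);
ulceration 25 yes / 26 no / 16 unknown. Count-based marginals are matched
*exactly* for every seed — assignment is a seeded permutation of the
specified counts, not sampling — and the generator restores the caller's
RNG state.

Only marginals are published, so the joint distribution is independent
assignment except hard clinical constraints: pT = T0 marks the 13 MUP
patients (no primary ⇒ no Breslow thickness, ulceration recorded as
"unknown", sentinel excision not performed, and the unknown-ulceration
budget is spent on MUP patients first); Breslow thickness is drawn
uniformly inside its pT band (T1 ≤ 1 mm up to T4 > 4 mm); resection
status is R0 throughout, mirroring the cohort inclusion criterion. Ages
come from a piecewise-linear quantile model through (min 25, Q1 48,
median 60, Q3 70, max 90) — a modeling choice targeting the published
median and IQR, not a published distribution. Diagnosis dates are uniform
over Nov 2018–Aug 2023 so patients are at most in their fifth follow-up
year at the reference date. Fields with no published distribution at all
(sonography findings, SLNE positivity, capsular breakthrough, metastasis
detection, mitotic rate) use fixed plausible rates chosen once
(remarkable sonography 0.45, SLNE-positive 0.6, capsular breakthrough
0.2, metastasis 0.05, mitotic rate Gamma(2, 1.5)); they shape which
branches the synthetic cohort exercises but no acceptance-level statistic
depends on them. Per-parameter missingness is an independent Bernoulli
dial, default 0 (the study curated its data to completeness before
simulating).

What passing tests on this cohort do show: the engine, graph and
accounting behave correctly under the published marginal conditions. What
they cannot show: anything about the real cohort's joint structure, its
missingness pattern, or the hospital's exact branch logic — the published
per-decision-point pass counts are therefore *not* reproduction targets,
and the cohort-level checks are structural (conservation, determinism,
marginal fidelity) by design.

## The completeness and concordance statistics

Clinician relevance percentages are banded as less (0–33.3%), moderate
(33.4–66.6%) and high (66.7–100%); band membership is decided on values
rounded half-up to one decimal, so the printed closed ranges partition the
scale without a gap. The per-decision-point completeness rate is

$$\mathrm{rate} = 100 \times \frac{|\{\text{highly relevant}\} \cap \{\text{used by the algorithm}\}|}{|\{\text{highly relevant}\}|}$$

rounded half-up to one decimal, with "used" meaning explicitly marked
parameters, optionally widened to implicitly used ones (parameters
subsumed by the algorithm's tumor-stage input at the tumor-conference
decision). Free-text "additional data" mentions stay out of the
denominator; the tumor-thickness mention at the first decision situation
(named by 90% of respondents but intentionally not offered as a
selectable answer) is carried as an additional row, which is what makes
that decision point's rate 100% rather than 80%. An empty highly-relevant
set is defined as a vacuous 100% and logged. On the shipped survey
transcription the rates are 100.0 / 100.0 / 87.5 / 30.8 (84.6 with
implicit usage) for the four surveyed decision situations, and the
mismatch sets are {resection status} and {age at primary diagnosis, date
of first diagnosis}.

Next-step concordance compares the simulation's selected option(s) with
the clinicians' per-option response counts. An option **agrees** when the
simulation selected it and every respondent did too, or when the
simulation did not select it and no respondent did; any deviation flags
the option for discussion. Strict unanimity — rather than a majority
rule — is what reproduces the published flag pattern, where a single
deviating respondent (traceable to one participant who answered only one
option per block) flags an option even at 8/9 agreement. Percentages are
count/respondents rounded half-up to one decimal (respondents: 10 at the
first decision situation, 9 thereafter).

## Problem sizes and numerical choices

The test suite and the analysis scripts run the full 67-patient cohort
(a traversal is a few dozen steps, so a cohort simulates in seconds); the
age-distribution check scales the count marginals by 50 to n = 3350 so
the quantile model is measured rather than asserted at small n.
Half-up rounding is implemented as `floor(10x + 0.5 + 1e-9)/10`; the
epsilon guards against binary representation of values like 84.55 and is
three orders of magnitude below the one-decimal resolution it protects.
Stage comparisons use the fixed AJCC total order 0 < IA < IB < IIA < IIB
< IIC < IIIA < IIIB < IIIC < IIID < IV. Undated extraction candidates
sort before any dated one. Seeds are plain non-negative integers fed to
R's default RNG inside a state-restoring wrapper.

## Known limitations

* Graph topology and the DP8/DP10/DP16–DP21 predicates are
  reconstructions (see above); the config format exists precisely so a
  hospital can substitute its own logic.
* The synthetic cohort's joint distribution is independent beyond the
  hard constraints listed; in particular ulceration is *not* linked to
  the pT a/b suffix, which real AJCC coding would imply, because the
  published marginals themselves are not jointly consistent (28 b-suffix
  patients vs. 25 ulcerated).
* The survey transcription carries the published numbers unmodified,
  including the known single-respondent artifact; no correction is
  attempted because the raw responses are not available.
* Tumor stage is consumed as a recorded field; the package does not
  re-derive AJCC stage from pT/N/M.
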