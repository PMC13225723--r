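---
title: "Modeling CoCM billing eligibility and reimbursement potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CoCM billing eligibility and reimbursement potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocmbill)
```

## The problem

The Collaborative Care Model (CoCM) adds a care manager and a psychiatric
consultant — here called the behavioral health consultant (BHC) — to the
primary-care team. Since 2017, Medicare reimburses CoCM through dedicated
CPT/HCPCS codes, but each code carries service requirements (what must
happen in the month) and time requirements (how many care-manager minutes
the month must contain). When CoCM is delivered to complex populations,
much of the documented effort — outreach before the patient engages,
long months of coordination — falls outside what the codes cover.

`cocmbill` turns a care-management registry (one row per documented
activity: initial and follow-up care-manager encounters, contact attempts,
BHC consultations) into patient-calendar-month billing decisions, dollar
reimbursement at a configurable fee schedule, and summary surfaces: percent
of minutes billable, revenue per hour of care management, and taxonomies of
why minutes were unbillable. A seeded synthetic registry generator makes
the whole pipeline testable without patient data.

## The billing model

**Unit of analysis.** The calendar month per patient, because the codes'
requirements are stated per calendar month. Only activity inside the
intervention window contributes: from the randomization (enrollment) date
to six calendar months later, half-open and date-anchored
(`add_months(r, 6)` is excluded). A fixed-day window (183 days by default)
is available via `window_type = "days"` for sensitivity work; the
calendar-month reading is the default because the billing rules themselves
are monthly. Entries falling inside the final calendar month but past the
six-month date are truncated at the date, not the month.

**Service requirements.** A month is CoCM-eligible when it has a
care-manager encounter, a BHC consultation, and complete measurement-based
care (MBC; at least 50% of a measure's items answered, threshold
configurable, or a precomputed completeness flag). The registry-entry
requirement is automatically satisfied for any emitted month, since a month
exists only because entries exist. A month missing only the BHC
consultation is still eligible for the general Behavioral Health
Integration (BHI) codes, which require the encounter and MBC but not the
consultation; their continuity-of-care requirement is treated as always met
because every patient has an assigned care manager. The code-specific
extras (treatment planning, care coordination, relapse prevention) map onto
these same flags, so they add no further checks. Verbal consent to CoCM is
modeled as always satisfied: it is obtained during initial engagement for
every patient, so it never binds.

**Time requirements.** Ranged codes follow the CPT half-plus-one rule:
billable once minutes reach `floor(max/2) + 1`.

| Code  | Setting  | Time model | Frequency |
|-------|----------|------------|-----------|
| 99492 | non-FQHC | 36–70 min  | once, first CoCM month |
| 99493 | non-FQHC | 31–60 min  | once per subsequent month |
| 99494 | non-FQHC | 16–30 min add-on | up to twice per month |
| G2214 | non-FQHC | 16–30 min  | once per month, only when 99492/99493 cannot be billed |
| 99484 | non-FQHC | set 20 min | once per month, general BHI |
| G0512 | FQHC     | set 70 min first / 60 subsequent | once per month |
| G0511 | FQHC     | set 20 min | once per month, general BHI |

**Precedence.** For a CoCM-eligible non-FQHC month the engine bills the
base code (99492 until it has been billed once, then 99493), credits it up
to its maximum, then up to two 99494 add-ons from residual time of 16+
minutes; any remaining excess is over-maximum. A month under the base
minimum falls back to G2214 and then — only when G2214 is excluded and at
least 20 minutes are present — to 99484; time under every minimum is
under-minimum. FQHC months bill G0512 when they reach its qualifying
minimum and G0511 otherwise. BHI-only months bill the set-amount general
BHI code. When the code a month would have used is excluded by the
restrictive scenario, those would-be credited minutes are categorized
`restricted`; months meeting no service requirements are
`missing_services`. Reasons are assessed in that order — services first,
then scenario availability, then time thresholds — so each minute lands in
exactly one bucket and `billable + unbillable == total` in every month.

Three rules deserve comment because the written guidance admits more than
one reading; each is a package-level decision, switchable where noted:

* *Under-minimum initial months.* Guidance supports both the CoCM
  management code and the general BHI code here. The engine prefers G2214
  (all CoCM services are present and it is the CoCM-specific code) and
  uses 99484 only when G2214 is unavailable. In the two preset scenarios
  the choice is invisible: expansive has G2214, restrictive has neither.
* *The 31–35-minute initial gap.* An initial month of 31–35 minutes is
  under the 99492 minimum but over the G2214 maximum. The engine bills
  G2214 crediting 30 and marks only the excess over-maximum, consistent
  with how the set-amount codes treat excess.
* *G0512 crediting.* The FQHC CoCM code covers a set quantum (70 minutes
  for the patient's first billed instance, 60 after). By default qualifying
  months credit exactly that quantum with the excess over-maximum
  (`g0512_crediting = "set_amount"`); crediting actual minutes is available
  as `"actual_minutes"`. The first-instance 70-minute threshold attaches to
  the first *billed* G0512, not the first engaged month.

**Initial-code deferral.** When a patient's first CoCM-eligible month is
under the initial-code minimum, the fallback code is billed and 99492
remains available the following month. Billing G2214, 99484 or G0511 never
consumes the initial code and never starts the follow-up (99493) sequence.

**Pre-engagement time.** A patient's engagement month is the first calendar
month meeting all three CoCM criteria. Unbillable minutes in strictly
earlier months (all months, for never-engaging patients) are tallied as
pre-engagement outreach — a month can be BHI-billable and still
pre-engagement; only its unbillable minutes count toward the tally.

## Pricing and summaries

Revenue is per billing instance, at the 2024 Medicare non-facility amounts
shipped as the `"medicare_2024"` schedule (99484 \$54.92, 99492 \$153.12,
99493 \$139.81, 99494 \$59.25, G2214 \$57.25, G0511 \$83.88, G0512
\$146.57). Arithmetic is integer cents; display rounds half-up — cents for
currency, integers for percents, one decimal for ratios. Revenue per hour
divides total revenue by *all* documented minutes in scope (billable plus
unbillable) over 60; a billable-hours denominator is deliberately not the
default because the quantity of interest is the return on every documented
care-manager hour. The Medicaid-style schedules (`"medicaid_min"`,
`"medicaid_max"`) are placeholders requiring user-supplied state rates —
per-code state values are not constants of the package.

Scenario knobs: the expansive preset assumes all seven codes reimbursable;
the restrictive preset drops 99484 and G2214 for non-FQHCs (the FQHC codes
are retained in both, so FQHC results are scenario-invariant). Contact
attempts carry no duration in the registry and are imputed at 5 minutes
each (10 is the plausible maximum, the second sensitivity setting). The
third sensitivity knob assumes a fraction of billable months goes unbilled
in practice: the default `deterministic_scaling` reading multiplies every
month's revenue by `1 - fraction` (reproducible, and exact for a fraction
read as a bound); `random_month_drop` zeroes a seeded Bernoulli subset of
billable months, equal in expectation. The adjustment is applied after
pricing, within each scenario.

## The synthetic generator

`simulate_registry()` emulates the statistical structure the analysis
consumes; `fixture_trial_scale()` additionally forces the per-type minute
totals to a published trial-scale registry summary (10,216 initial, 45,839
follow-up, 11,206 consultation minutes and exactly 4,747 contact attempts,
90,996 minutes in all at 5 minutes per attempt) by post-hoc scaling, and is
labelled synthetic accordingly.

Design choices, each the simplest structure consistent with the marginal
summaries available:

* **Engagement delay** per patient is categorical over 0–5 pre-engagement
  months plus a never-engages mass (default 18%, matching the share of
  trial patients without a care-manager encounter). The remaining mass
  (0.40, 0.14, 0.10, 0.08, 0.06, 0.04) was set once so that pre-engagement
  outreach forms a visible share of documented time. Pre-engagement months
  contain only contact attempts; the first engaged month contains the one
  initial encounter with complete MBC and at least one BHC consultation by
  construction, so the delay parameter equals the downstream
  pre-engagement month count exactly.
* **Counts** are Poisson per calendar month (attempts 2.1 in every month;
  follow-ups 1.2 and consultations 0.95 per engaged month, on top of the
  guaranteed initial-month review) — chosen to land near the trial-scale
  entry counts at 381 patients.
* **Durations** are normal, truncated at 1 minute and rounded to whole
  minutes. The stated mean/SD (initial 33/17, follow-up 24/14, consultation
  7/5) describe the *emitted* minutes: the parent normal is moment-matched
  numerically, so sample moments recover the parameters without truncation
  bias. `estimate_sim_params()` recovers durations, rates and the MBC
  completion probability (default 0.85) within 5% relative error at 2,000
  patients.
* **Independence** is assumed between consultation presence and encounter
  intensity; the real joint distribution is unknown.

What passing tests on this generator do *not* show about real registries:
the generator has no seasonal or clinic-level structure, no correlation
between month length and activity, and its monthly minute totals near the
billing thresholds (hence the over/under-minimum split and the
pre-engagement minute share) need not match any particular trial's. Results
on synthetic data validate the rules engine and the accounting identities,
not the empirical magnitudes.

## Numerical and degenerate-input choices

Calendar-month arithmetic clamps the day (Jan 31 + 1 month = Feb 28/29).
Zero-minute encounters are legal and fall in the under-minimum bucket of
service-eligible months. Months with no entries are never emitted — no
imputation of assumed-missing activity. Rows violating the data model are
rejected individually with row-level diagnostics rather than failing the
file. An empty scope produces a zero report with an explicit `empty` flag.
Revenue is kept in cents as integers until an unbilled-fraction scaling
introduces fractional cents, which are preserved unrounded internally so
the deterministic 40% sensitivity is exactly linear.

## Worked example

```{r example, eval = FALSE}
reg <- simulate_registry(sim_params(n_patients = 381, seed = 1))
grid <- scenario_grid(reg$entries, reg$patients)
grid$expansive$reports$combined
ineligibility_breakdown(grid$expansive$decisions)
```

Problem sizes used by the shipped checks: the rules engine is compared with
a brute-force enumeration reference on 10,000 randomized months across both
settings and scenarios; conservation and monotonicity suites run on
150-patient registries; parameter recovery uses 2,000 patients; the
unbilled-fraction expectation check averages 200 seeds.

## Known limitations

The engine models code assignment, not payer adjudication: no claims
formatting, modifiers, place-of-service logic, or commercial-payer rules.
Costs (wages, fringe, overhead) are out of scope, so revenue per hour is
not a margin. MBC completeness by instrument-specific scoring guidance is
not implemented — only the fraction-of-items threshold or a precomputed
flag. Post-2024 FQHC rule changes are not reflected.
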