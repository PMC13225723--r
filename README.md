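# cocmbill

Billing eligibility and reimbursement potential for the Collaborative Care
Model (CoCM).

Primary-care teams delivering CoCM — a care manager plus a psychiatric
consultant supporting the usual providers — can bill dedicated Medicare
CPT/HCPCS codes, but each code binds a patient's calendar month to service
requirements (care-manager encounter, consultant caseload review, complete
measurement-based care) and time requirements (ranged codes under the CPT
half-plus-one rule, `min = floor(max/2) + 1`, or fixed 20/60/70-minute
quanta). `cocmbill` is for health-services researchers and health-system
analysts who want to ask: *of the care-manager time a registry documents,
how much could have been billed, under which codes, for how many dollars
per hour of care management — and why was the rest unbillable?*

The package takes a care-management registry (one CSV row per documented
activity) and a patient table, aggregates activity into patient
calendar months over a six-month intervention window, evaluates CoCM and
general Behavioral Health Integration (BHI) service requirements, assigns
codes under the time rules — base code 99492/99493 (or FQHC G0512), up to
two 99494 add-ons, G2214/99484/G0511 fallbacks, deferral of the initial
code past under-minimum months — prices the result against a fee schedule
(2024 Medicare rates built in), and reports billable shares, revenue per
documented hour, and ineligibility taxonomies under expansive/restrictive
code-availability scenarios and three sensitivity settings. A seeded
synthetic registry generator makes every stage testable without patient
data.

## Worked example

```r
library(cocmbill)

reg  <- simulate_registry(sim_params(n_patients = 381, seed = 1))
grid <- scenario_grid(reg$entries, reg$patients)
grid$expansive$reports$combined
```

```
CoCM reimbursement summary [combined, scenario: expansive, fees: medicare_2024]
  Patients / patient-months:        381 / 2179
  Total minutes:                    91,499
  Total hours:                      1,525
  Minutes eligible to bill:         49,519
  Percent of minutes eligible:      54%
  Potential reimbursement:          $129499.38
  Reimbursement per hour of CoCM:   $84.92
  Billable minutes by code:
    99484  2,620 min (131 instances)
    99492  9,204 min (140 instances)
    ...
  Unbillable minutes by reason:
    missing_services   17,096
    under_minimum      591
    over_maximum       24,293
    restricted         0
    not_billed         0
```

Of 91,499 documented minutes, 54% were billable under the expansive
scenario (every code reimbursable), yielding $84.92 per documented
care-manager hour at 2024 Medicare rates; the largest losses were months
missing a service requirement and time beyond the monthly code maxima.
Digging into the unbillable side:

```r
ineligibility_breakdown(grid$expansive$decisions)
#> $service_gap_minutes            # minutes by missing CoCM component(s)
#>        BHC    BHC+MBC CM+BHC+MBC     CM+MBC        MBC
#>      16595        754       8880       5109       2353
#> $pre_engagement_share_of_total
#> [1] 0.0797                       # outreach before first engaged month
```

Months missing only the consultant review (`BHC`) remain billable to the
general BHI codes; the restrictive scenario (`grid$restrictive`) removes
99484 and G2214 and shows the revenue at stake. Real registries are read
with `read_registry("registry.csv", "patients.csv")` and run through the
same `run_scenario()` / `scenario_grid()` calls; a thin command-line
wrapper lives at `inst/cli/cocmbill.R` (subcommands `simulate`, `run`,
`grid`, `sensitivity`, `report`).

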