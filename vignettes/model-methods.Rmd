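---
title: "Model methods: NBI-guided targeted biopsy vs HD-WLE with the Seattle protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: NBI-guided targeted biopsy vs HD-WLE with the Seattle protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrettcca)
```

## The decision problem

Barrett's esophagus (BE) is surveilled endoscopically because it can progress
through low-grade (LG) and high-grade (HG) dysplasia to esophageal
adenocarcinoma (EAC). The surveillance standard — high-definition white-light
endoscopy (HD-WLE) with the Seattle protocol of random four-quadrant biopsies
every 2 cm — is biopsy-intensive. Narrow-band imaging (NBI) guides *targeted*
biopsies, cutting the average specimen count per procedure from 7.6 to 3.6 at
comparable per-patient diagnostic accuracy. This package quantifies the
economic consequences for NHS England (and for a single hospital) of adopting
NBI, over a 7-year horizon, via a decision tree for the diagnostic phase and
a 6-month-cycle Markov model for disease progression, and cross-checks every
cohort-level expectation with an individual-patient microsimulation.

## Model structure

**Cohort.** 161,657 patients attend endoscopy in year 1, growing 20% per
year. The exact geometric sequence is carried internally and rounded half-up
only for display; this convention reproduces both the published yearly
populations and their 7-year total (2,087,946) exactly, whereas rounding each
year before compounding drifts by 1–5 on the totals. Costs after year 1 are
discounted at 3.5% per year (`factor[t] = 1.035^-(t-1)`); event counts are
never discounted.

**Entry states.** The entering cohort is distributed over ND/LG/HG/EAC using
the source cohort's integer counts (1791, 751, 106, 48 of 2,696), not the
rounded percentages: the published eradication count (77,331) is only
reproduced by the exact fraction 106/2696.

**Diagnostic tree.** Dysplastic patients test positive with sensitivity
0.942, non-dysplastic patients test negative with specificity 0.944
(per-patient level; both arms identical by design). Grade assignment among
detected dysplastics is taken as correct because only binary accuracy is
available. False positives are labelled LG — they enter intensive
surveillance but are never resected, the conservative reading of a tree that
routes resection to HG only. Detected HG and EAC patients are treated (EMR +
RFA, or cancer treatment, both billed at the GBP 2,101 tariff). The
*reported* successful-eradication count is the detected-HG count; the strict
count (x 0.949 eradication rate) is what the progression module uses. An
optional histopathology confirmation layer (sensitivity 1.0, specificity
0.629) can prune false positives; it is off in the base case, which is
reproduced without it.

**The NBI arm is a mixed arm.** 84% of procedures use NBI, 16% remain
HD-WLE. All per-procedure quantities (biopsies, endoscopy adverse-event
rates, staff micro-costs) blend linearly: 0.84 x 3.6 + 0.16 x 7.6 = 4.24
biopsies per procedure, the only convention that reproduces the published
NBI-arm biopsy total of 8,852,892. The comparator is 100% HD-WLE.

**Adverse events.** Endoscopy-related strictures (0.01%), perforations
(1.4% NBI / 3.0% HD-WLE) and bleedings (0.2% / 0.5%) accrue per procedure by
default; the accounting basis is a parameter (`per_procedure`, `per_biopsy`,
`per_treated`) because the publication's own AE counts are not reproducible
under any single basis — the implied exposure differs by event type.
Treatment-related events (33.5% strictures, 1.3% perforations, 7.5%
bleedings) accrue per treated patient in both arms.

**Markov progression (long-term scenarios).** Fourteen 6-month cycles with
the published transition matrix (ND 0.95/0.05; LG 0.9318/0.0682; HG
0.9048/0.0952; EAC absorbing; no regression, no mortality). Patients
believed non-dysplastic — true negatives *and* missed dysplastics — attend
surveillance every 36 months and are re-tested with the arm's accuracy at
each visit; no detection occurs between visits. Diagnosed LG, false
positives and post-treatment patients attend every 6 months; the paper
states post-treatment surveillance is 6-monthly, so eradicated patients
re-enter the 6-month pool at the ND state rather than dropping to the
36-month interval. Cancer-management cost (GBP 7,647/year, halved per
cycle) accrues for *diagnosed* EAC only: charging management costs for
cancers nobody has found would be incoherent, and the publication does not
state its bookkeeping. Each entry-year cohort is followed from its entry
year to the end of the horizon, with cycle `c` falling in calendar year
`y + ceiling(c/2) - 1` for discounting.

## Costing

Under the **NHS perspective**, endoscopy and treatment are booked at their
tariffs (GBP 517 and 2,101) — staff and consumable micro-costs are covered
under tariff — plus histopathology (GBP 82 per biopsy), adverse-event
management (GBP 392 stricture/bleeding, 2,852 perforation) and capital.
Under the **hospital perspective**, procedures are micro-costed (staff time
x hourly rates + consumables; HD-WLE staffing costs GBP 186.99 per
endoscopy, NBI 167.72, because nurse non-contact time scales with the biopsy
count), tariffs are booked as income, and the margin (income minus cost) is
reported alongside the cost difference.

**Capital equipment.** The NBI arm upgrades the Olympus-installed estate
(84% of 249 hospitals, 3.25 rooms each): the 17% of systems not yet
NBI-capable, the 60% of scopes not yet HD, and two training days for half
the endoscopists. One-off purchases are amortized as equal annual charges
over 7 years and discounted like any other cost (the order is commutative).
Both arms accrue 2.9%/year scope replacement; the NBI arm applies it only to
the 16% of the estate it did not just upgrade, on the reasoning that newly
purchased scopes need no replacement within the horizon. Maintenance
contracts are hospital-perspective costs only. The published capital totals
(GBP 103.9 / 35.6 mln) exceed what these stated formulas yield (about 52.9 /
18.1 mln); the residual's composition is not stated, so the package reports
its formula-based totals and checks the direction of the increment instead.

## Analyses

* `cost_consequence()` — the side-by-side category/outcome table; money
  discounted, counts undiscounted; relative differences are fractions.
* `budget_impact()` — yearly expenditure per arm; rows sum exactly to the
  cost-consequence totals (tested as an identity).
* `icer()` — incremental ratio with dominance labels; displayed as
  thousands of GBP to 3 significant figures. Equal-accuracy comparisons
  yield "cost-saving-equal-effect", never a finite ratio.
* `run_scenario()` / `run_all_scenarios()` — the six-scenario grid crossing
  accuracy level (per-patient / per-lesion), perspective (NHS / hospital)
  and long-term follow-up (NHS only). Per-lesion scenarios use the
  per-lesion operating characteristics (NBI 0.890/0.800, HD-WLE
  0.791/0.810) and model a lesion pool of λ lesions per dysplastic patient;
  λ is a parameter (`accuracy.lesions_per_patient`, default 1) because
  lesion multiplicity is not published — scenario *directions* are
  therefore meaningful while the published lesion-count magnitudes depend
  on the unstated λ.
* `owsa()` — deterministic one-way sensitivity analysis; every input varied
  ±10% (discount rate: 2.0%–5.0%), each bound re-running the full pipeline,
  ranked into a tornado. Accuracy bounds should be the source study's 95%
  confidence interval, which is not published; ±10% with clipping at 1 is
  used unless bounds are supplied.
* `equal_ae_analysis()` — the special analysis equalising endoscopy AE
  rates across arms; its result equals the base saving minus the AE
  component exactly (algebraic identity, tested on perturbed parameter
  sets).

## Microsimulation oracle

`simulate_patients()` draws i.i.d. patients with exactly the cohort model's
probabilistic structure: state from the entry distribution, technique by
market share (a Bernoulli per patient, so the 4.24 blend is an expectation),
detection and adverse events as Bernoulli draws, integer biopsy counts as
`floor(b) + Bernoulli(frac(b))` so means match the per-procedure counts, and
in long-term mode a stochastic walk of the transition matrix with the same
visit schedule as the cohort engine. A single seeded R RNG stream drives the
vectorized draws; results are reproducible given `(n, seed)` and the
caller's RNG state is restored afterwards. `validate_against_cohort()`
compares every sample mean to its deterministic expectation at a 3-standard-
error band; the test suite runs this at n = 10^5 for both arms and checks
convergence over n = 10^3..10^5.

What the microsimulation does *not* emulate: patient heterogeneity (age,
segment length, operator variability), regression of dysplasia, mortality,
or recurrence after eradication — none of which the cohort model contains
either. Agreement between the two engines therefore validates the
implementation, not the model's fidelity to real surveillance populations.

## What is and is not reproduced

Reproduced exactly: the yearly populations and their total; the biopsy
totals, difference and −44.2%; the per-patient histology costs (295.2,
623.2, and ~348 for the mixed arm); 77,331 eradications; the ICER
arithmetic on the published scenario results; the equal-AE decomposition.

Not reproduced, by documented conventions gaps in the source: the grand
cost totals (our 1,962 / 2,507 vs 1,966 / 2,424 GBP mln — the adverse-event
and capital categories carry the difference), the AE counts, the
"correctly identified" count (our TP+TN convention gives 1,969,620 vs the
published 1,934,602), the capital totals, and the long-term scenario
magnitudes (our follow-up engine surveils every entering cohort, which
yields larger volumes than the published 349.2/331.5 mln savings and 1,615
avoided cancers). For these the package asserts properties instead:
direction of every difference, exact additivity identities, Markov
invariants, and microsimulation agreement.

## Problem sizes and numerical choices

The test suite uses microsimulations of 2x10^4–10^5 patients (seconds on one
CPU; standard errors small enough that a 3-SE band detects a 1.5x corruption
of any expectation). Fractional expected counts are carried everywhere
internally; rounding is half-up and happens only in report emitters.
Probability bounds in the sensitivity analysis are clipped to [0,1] with a
warning. Degenerate inputs (zero growth, zero rates, single-year horizons,
empty cohorts) are exercised in the tests.
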