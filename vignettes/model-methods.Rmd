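---
title: "Model and methods: small-bowel toxicity after pelvic radiotherapy"
author: "sbtoxecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: small-bowel toxicity after pelvic radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbtoxecon)
```

## The decision problem

Late small-bowel (SB) toxicity after pelvic radiotherapy for rectal
cancer produces chronic diarrhea (grades 1–2) and, in severe cases,
obstruction, bleeding or perforation (grades 3–4) with hospital
admissions, surgery and excess mortality. More conformal delivery lowers
the dose to healthy bowel and hence the normal-tissue complication
probability (NTCP). The package asks: over the remaining lifetime of a
survivor cohort, what do 3D-CRT, IMRT and IMRT/IGRT cost society in SB
toxicity alone, and what quality-adjusted survival do they deliver?
Results are reported as incremental cost and incremental QALYs against
3D-CRT separately, not as a ratio: when one technique is both cheaper and
more effective, a single ICER hides the structure of the result.

## Model structure

The core is a cohort state-transition model with half-yearly cycles
(`cycle_length_years = 0.5`) run until age 100 or death. All patients
start symptom-free in *post-treatment*. In each cycle they face four
grade-specific event probabilities; grade 1–2 events resolve through a
pharmaceutical decision tree, grade 3–4 events through a hospitalization
tree. Events move patients permanently out of *post-treatment* into a
*symptom management* state indexed by (a) the pathway that treated the
last event — pharmaceutical, supportive or surgical — and (b) the number
of prior recurrences (0–4). From management, patients can suffer
recurrent events: these enter one-cycle *tunnel* states (no
self-transition) and resolve through the hospitalization tree in the next
cycle, because a recurrence means obstruction or perforation and
therefore admission. Two absorbing states collect SB-toxicity deaths and
deaths from other causes.

Design choices made where the structure was genuinely open:

* **First-event risk applies only in post-treatment.** Re-exposing event
  survivors to the ≈16.6% per-cycle first-event probability (3D-CRT)
  would give an implausible cumulative incidence; after any event,
  further risk is carried by the recurrence probabilities.
* **Recurrence levels cap at 4**, the deepest level priced in the
  parameter table; further recurrences reuse level-4 probabilities.
* **Pharmaceutically managed patients** have no printed recurrence
  probabilities of their own; they borrow the non-operative
  ("supportive") values, consistent with the surgical/non-operative
  dichotomy in the evidence, and configurable via
  `pharma_recurrence_source`.
* **Failed pharmaceutical management still ends the cycle in symptom
  management** (recovery from grade 1–2 is assumed); escalation happens
  only through later recurrence. `pharma_failure_escalates = TRUE`
  routes persistent failures through the hospitalization tree instead,
  as a sensitivity-exploration knob (its payload accounting is
  deliberately additive and therefore approximate).
* **Competing risks within a cycle:** background death is applied first
  and SB dynamics apply to survivors. Alternative orderings differ at
  O(q·p), which is negligible at these magnitudes.
* **Recurrence accounting:** the admission, its cost, sick leave and the
  one-cycle disutility are booked at the cycle in which the recurrence
  occurs (tunnel inflow); the tunnel exit in the following cycle only
  distributes destinations. This keeps cumulative admission counts
  aligned with event occurrence.

## Hazard conventions

Probabilities and rates interconvert assuming a constant hazard:
`r = -log(1 - p)/t`, `p = 1 - exp(-r t)` (`prob_to_rate()`,
`rate_to_prob()`; round-trip exact to 1e-12).

* **NTCP scaling acts directly on the probability scale.** The reference
  grade probabilities (IMRT/IGRT) are multiplied by
  `NTCP_technique / 0.180` with the unrounded fractions 0.265 and 0.395:
  5.088 × 0.265/0.180 = 7.491 reproduces the tabulated IMRT values to
  three decimals, whereas scaling on the rate scale would give 7.40.
  Rate-scale scaling is the more orthodox choice, but the package follows
  the arithmetic that generated its own parameter table. The 0.265 figure
  is adopted for IMRT because it is the only value consistent with that
  table (a 28.5% figure circulating for the same quantity is not).
* **Hazard decay.** Event hazards are flat for the first
  `decay_onset_years = 5` years, then the *rate* is multiplied by
  `0.75^w` where `w` is the number of whole years elapsed past the
  plateau — a stepwise annual decline, right-continuous at the boundary
  (`decayed_probability()`). By default decay applies to first-event
  probabilities only (`decay_on_recurrence = FALSE`): recurrence risk is
  conditioned on the treatment pathway, not on time since treatment.
* **Background mortality** converts annual life-table `q` to half-years
  by `1 - (1 - q)^0.5`.

## Cycle trees and their payloads

The trees are reconstructed from the clinical pathway description:
loperamide (92.80% success) → antibiotics (44.44% of failures, 41.85%
success) / bile acid sequestrants (55.56%, 30.87%); hospitalization →
surgery (22.80%, case fatality 3.783%) / supportive care (77.20%, case
fatality 0.837%). Survival branches are taken as complements of the
printed death probabilities so every chance node is normalized to 1e-9
(the printed survival/death pairs do not sum to exactly 100%).
`collapse_tree()` computes exact expectations by path enumeration; a
million-walk Monte-Carlo oracle in the test suite confirms them.

Drug resource use is not itemized in the available sources, so a course
is an explicit configuration: `course_days = 90` at 2/3/4 units per day
for loperamide/antibiotics/sequestrants — conservative defaults chosen
once, varied only through the sensitivity machinery. Sick leave attaches
as 14.550 days per first/recurrent event (multiplied by 1.5 on
hospitalization paths, since the 0.500 factor is labelled *additional*)
plus 9.650 days on each entry into symptom management — once on entry,
not per cycle spent there, which would implausibly dominate all other
costs. The 9.650 base value is used as printed even though the lognormal
location recorded next to it (e^2.677 ≈ 14.5) disagrees; the base-value
column is taken as authoritative throughout. The third relative
disutility (−38.7%) is attached to the surgical pathway: the source
labels two rows identically for supportive treatment, but the pathway
enumeration (pharmaceutical, supportive, surgery) and the ordering make
the surgical reading the coherent one.

## Valuation

Per cycle, costs accrue as event flows × collapsed-tree expectations
(drug and admission components kept separate), plus productivity losses:
sick-leave days × daily wage (€250.118) × activity rate (75.10%)
restricted to ages below `retirement_age = 65`, and a human-capital
valuation of SB deaths — annual wage (€55,025.90) × activity rate ×
remaining working years, discounted within the annuity at the cost rate.
QALYs weight end-of-cycle survivors by an age-interpolated baseline
utility times 0.5; surviving event flows lose the pathway's relative
disutility multiplicatively for that one cycle. Discounting uses 3.0%
(costs) and 1.5% (utilities) with mid-cycle timing
(`t = (k + 0.5) × 0.5`) by default; `half_cycle = FALSE` switches to
start-of-cycle valuation. The convention is a package choice — the
underlying evidence does not state one — and flips no sign in any
reported comparison.

## Sensitivity machinery

* **One-way (tornado):** each parameter at 70% and 130% of base
  (`dsa_low`/`dsa_high`), full model re-run at each end, both incremental
  outcomes reported, rows sorted by spread. Probabilities are capped at 1
  with the cap logged.
* **Probabilistic:** 1,000 joint independent draws by default. The
  distribution columns of the parameter table are internally inconsistent
  for several rows (beta shapes whose mean is far from the base value; a
  shared beta for a probability and its complement; gamma scales swapped
  between the two drug-cost rows; lognormals with no dispersion printed).
  The default `calibrated` mode therefore re-derives each distribution
  around the base-case mean: beta by method of moments with effective
  sample size `beta_ess = 100`, gamma keeping the printed shape with
  `scale = base/shape`, lognormal with `sigma_log = 0.25` and
  `meanlog = log(base) - sigma²/2`. This keeps the probabilistic cloud
  centred on the base case, which is what a sensitivity analysis around a
  base case is for; `verbatim` mode reproduces the printed parameters
  unchanged for comparison. Grade probabilities, flagged without
  distributions of their own, vary through beta-calibrated draws of each
  technique's NTCP divided by the 0.180 reference — a single
  multiplicative uncertainty factor on the grade vector. Draws are
  independent across parameters; no correlation structure is available to
  impose.

## Synthetic population fixtures

The three external inputs are generated, not downloaded:

* **Life table:** Gompertz–Makeham,
  `qx = 1 - exp(-(λ + a·e^{b·age}))` with λ = 5e-4, a = 2e-5, b = 0.095 —
  remaining life expectancy ≈ 17 years at age 70, a plausible
  contemporary Western European schedule. `make_life_table(0, 0)` gives
  the immortal cohort used by zero-mortality analyses.
* **Incidence mix:** discretized normal over ages 25–99, mode 70,
  SD 12 years, normalized; optional seeded lognormal jitter roughens the
  weights the way registry counts are rough.
* **Utility curve:** linear decline from 0.92 (age 25) to 0.74
  (age 100), within [0,1] and non-increasing, interpolated at half-year
  ages.

These fixtures emulate the *structure* of national registry data
(monotone-in-age mortality, late-adulthood incidence peak, age-declining
population utility norms), not any country's values. Consequently,
absolute costs and QALYs depend on them, and the package's checks treat
absolute levels as order-of-magnitude quantities only; the quantities
that are fixture-independent — the NTCP-scaled transition probabilities,
tree expectations, and the zero-mortality admission counts — are checked
tightly. Passing tests therefore demonstrate internal correctness and the
right direction and magnitude of the comparative results, not calibration
to any specific population.

## Numerical choices and degenerate inputs

Chance-node normalization and cohort-occupancy conservation are enforced
at 1e-9; probability/rate round-trips at 1e-12. A probability of exactly
1 is rejected by `prob_to_rate()` (infinite rate). Event-probability sums
above 1 after scaling raise an error rather than renormalizing silently.
Zero-spread incidence places all mass at the mode; a zero-toxicity
parameter set reproduces life-table survival exactly and zeroes every
incremental.

## Problem sizes in the test suite

The suite exercises full lifetime horizons but keeps Monte-Carlo sizes
moderate by design: one-million-walk tree oracles, a 50,000-patient
microsimulation checked at cycles 10/40/100, 1,000 random draws for
transition-matrix stochasticity, and 60-draw probabilistic runs on a
two-age case mix for consistency checks; the full 25–99 incidence mix is
used for the headline economics. These sizes give Monte-Carlo standard
errors comfortably below the tolerances being asserted.

## Known limitations

* Long-horizon admission counts accumulate recurrences at level-4
  probabilities indefinitely; beyond ~20-year horizons for young cohorts
  this likely overstates admissions relative to the (unavailable)
  original tree topology. The 10-year counts, which drive the headline
  comparisons, are insensitive to this.
* Disutility during the hospitalization cycle of a recurrence is booked
  at the recurrence cycle rather than the tunnel cycle — one cycle
  either way.
* No NTCP dose–volume modelling: the three scalar NTCPs are inputs.
* No currency/inflation machinery: costs enter already in 2022 euros.
* Utilities enter as a precomputed curve; the questionnaire-mapping
  algorithm that produced the underlying disutilities is out of scope.
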