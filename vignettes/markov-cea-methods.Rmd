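---
title: "Model and methods: surgery vs thermal ablation for colorectal liver metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablatecea)
```

## The decision problem

Patients with oligometastatic colorectal cancer (3–5 liver metastases)
who are candidates for all three local treatments — surgical resection,
radiofrequency ablation (RFA) and microwave ablation (MWA) — face a
trade-off: surgery has the highest completeness of resection but higher
acute cost, a longer hospital stay, a worse first post-treatment month
and higher one-year mortality; the ablative techniques are cheaper and
gentler but carry higher hepatic recurrence risk (RFA more so than
MWA). The package estimates each strategy's expected discounted
lifetime cost and quality-adjusted life years (QALYs) for a US cohort
and compares strategies by dominance, incremental cost-effectiveness
ratios and net monetary benefit (NMB).

## Model structure

The model couples a 30-day short-run treatment model with an
annual-cycle Markov cohort model.

**Short run.** Each patient receives one treatment session that is
complete with probability `p_success_first` (0.99 / 0.93 / 0.97 for
surgery / RFA / MWA). An incomplete session is followed by a second
session, assumed complete, which repeats the full treatment cost —
acute procedure cost plus hospital stay (`hospital_days ×
cost_per_hospital_day`). The expected acute cost is therefore
`total_cost × (1 + (1 − p_success_first))`, accrued undiscounted at
time 0. The cost of the repeat session is our explicit assumption
(the second-session *success* is a stated input; its cost is not),
and it is configurable through the strategy table.

**Long run.** Four states: no recurrence, hepatic-only recurrence, any
other recurrence, death. All patients enter the Markov model
treatment-complete and recurrence-free. Per cycle, from the
recurrence-free state:

* death with the strategy's observed all-cause one-year mortality in
  cycle 1 (it *replaces* background mortality, being an all-cause
  observed figure), and with the life-table background probability
  `qx(age)` from cycle 2 on;
* hepatic recurrence and non-hepatic recurrence with constant annual
  probabilities;
* otherwise stay.

Recurrence states are mutually absorbing: no cross-over between them
and no return to the recurrence-free state, mirroring the clinical
reading that a detected recurrence defines the patient's subsequent
course in this model. Death is absorbing. The horizon is
`age_max − age_start` cycles (27 in the base case); beyond the life
table's last age `qx` is taken as 1, which also bounds the horizon for
user-supplied tables.

## Cycle arithmetic conventions

Two conventions of cohort models are genuinely open choices here, and
both are exposed as settings rather than hard-coded:

* **Recurrence-state mortality**
  (`background_mortality_in_recurrence`, default `FALSE`). The annual
  death probabilities with hepatic (12%) and non-hepatic (5%)
  recurrence are used as-is by default. The alternative combines them
  with background mortality as independent competing risks,
  `1 − (1 − qx)(1 − q_state)`. The published lifetime estimates for
  this comparison are reproduced by the as-is reading (the
  competing-risk variant depresses lifetime costs by 14–19% relative
  to them because patients leave the expensive recurrence states much
  faster at old ages); the competing-risk variant is the
  epidemiologically safer extrapolation for very old cohorts, and
  users running long horizons from young starting ages may prefer it.
* **Half-cycle correction** (`half_cycle_correction`, default `TRUE`).
  By default each cycle's rewards accrue on the average of
  start-of-cycle and end-of-cycle state membership, the usual
  first-order correction for events happening throughout the year.
  With the switch off, rewards accrue on start-of-cycle membership,
  which is what simple closed forms (the geometric annuity below)
  describe exactly. The default again follows the convention that
  reproduces the published estimates.

With both defaults, the base case lands within ±6% of the published
lifetime costs and QALYs for all three strategies and reproduces the
published dominance structure (MWA dominant) exactly. We note for
transparency that no constant-annual-probability convention we
examined reproduces the published *QALY differences* between surgery
and MWA at their stated magnitude; an additive sensitivity analysis of
the mortality and recurrence channels shows that gap is larger than
the inputs can generate under any accrual convention. The package
therefore reports what its stated inputs imply: MWA ahead of surgery
in QALYs by a narrow margin at age 73, with the advantage growing at
older starting ages and reversing below about age 70.

**First cycle.** The first month after treatment carries the
strategy's short-run utility (0.70 after surgery, 0.95 after
ablation); the remaining eleven months carry the recurrence-free
utility: cycle-1 utility `= qol_first_month/12 + 11/12 ×
utility_no_recurrence`. Recurrence and death risks apply from cycle 1.

**Discounting.** Cycle `t` rewards are discounted by
`(1 + r)^−(t−1)` with `r = 0.03`; the acute cost is undiscounted at
time 0. QALYs and costs are discounted identically.

**Validation without renormalisation.** Outgoing probability sums are
validated (`≤ 1`) at configuration load and again when each transition
matrix is built; infeasible inputs raise errors rather than being
silently rescaled.

## Parameters

Strategy-specific (surgery / RFA / MWA): first-session success 0.99 /
0.93 / 0.97; acute cost USD 2,421 / 1,493 / 1,493; hospital days 7 / 4
/ 4; first-month utility 0.70 / 0.95 / 0.95; one-year mortality 8.25%
/ 6% / 5.5%; annual hepatic recurrence 2.5% / 7.7% / 4%; annual
non-hepatic recurrence 5% (shared). Shared economics: per-diem USD
2,424; per-cycle long-term costs USD 855 (recurrence-free) and USD
3,935 (recurrence); utilities 1 / 0.65 / 0.19 / 0; recurrence-state
mortality 12% / 5%; discount 3%/yr; WTP USD 100,000/QALY; ages 73→100.
All costs are nominal 2018 USD; no inflation adjustment is applied.

The long-term cost inputs are tabulated in their source as monthly
amounts, but accruing them twelve times per annual cycle is
irreconcilable with the published lifetime totals they support (USD
855 × 12 per year alone would more than double the surgery total), so
the package applies them once per annual cycle.

## Life table

Background mortality comes from an annual life table (`age,qx` CSV).
Because no machine-readable US 2014 period table ships with the
package, the bundled table (`lifetable_us2014_synthetic.csv`) is
*synthetic*: generated by `generate_lifetable()` from the Gompertz
form `qx = 1 − exp(−a·e^{b·age})` with `a = 6.3e-5`, `b = 0.085`,
chosen once so that remaining life expectancy at age 73 is ≈ 13 years
— the ballpark of the US 2014 all-sex table. It is sex-averaged and
has no infant/accident hump, which is irrelevant for starting ages
60+. Analysts with access to a real national table should substitute
it via `read_lifetable()`; base-case results shift within a few
percent for tables with similar old-age hazards.

## Probabilistic sensitivity analysis

Uncertain parameters are drawn independently: gamma for costs, beta
for probabilities and utilities, parameterised by method of moments
from a mean and standard error. The spread of each distribution is not
reported with the inputs, so the package uses a relative spread
(default `spread = 0.2`): `se = spread × mean` for gamma and
`se = spread × min(mean, 1 − mean)` for beta. The `min` keeps
near-boundary probabilities feasible — `se = spread × mean` violates
the beta variance bound whenever `mean > 1/(1 + spread²)`, which the
success probabilities (0.93–0.99) do already at spread 0.2 — and is
symmetric under `p ↔ 1 − p`. Parameters whose mean sits exactly on a
boundary (the recurrence-free utility of 1) are degenerate and stay
fixed. Structural constants (discount rate, ages, WTP, second-session
success, hospital days) are never drawn. First-session success
probabilities are drawn by default and can be excluded
(`draw_success = FALSE`) since no uncertainty is tabulated for them.

Per iteration, one draw of each *shared* parameter (per-diem, state
costs, state utilities, recurrence-state mortality, non-hepatic
recurrence) is applied to all three strategies, preserving
common-random-numbers comparability; strategy-specific parameters are
drawn per strategy. Iteration `i` derives its draw from `seed + i`, so
results are bit-reproducible and independent of chunking; the
iteration loop itself is evaluated by an iteration-vectorised
recursion whose equality with `run_cohort()` is asserted by test.

Acceptability curves report, per willingness-to-pay value, the
fraction of iterations in which each strategy attains the maximal NMB
(ties to the lower-cost strategy, then input order). At WTP 0 this
ranks by cost alone; as WTP grows, by QALYs alone. Under the default
spread the MWA curve is above 0.9 at low WTP (its cost advantage is
near-certain) and declines toward ~0.6 at WTP 200,000, where the
near-tie in QALYs with surgery splits the iterations.

## Starting-age sweep

`age_sweep()` re-runs the model for starting ages 60–85 (only
`age_start` varies; treatment parameters have no modelled age
interaction) and reports cost, QALYs and NMB at the configured WTP.
With the default conventions MWA attains the maximal NMB from about
age 70 upward and surgery below it, with the two within ~1.5% of each
other throughout 60–69 — the model's crossover between surgical
efficacy (felt over a long remaining horizon) and ablation's lower
mortality and cost (felt immediately).

## Verification

* **Microsimulation oracle.** `run_microsim()` pushes individual
  patients through the identical short-run lottery and per-cycle
  transition matrices, accruing identical discounted rewards, using a
  single seeded uniform matrix indexed (patient, cycle) so results do
  not depend on evaluation order. The cohort model is the exact
  expectation of this process: tests require agreement within 3 Monte
  Carlo standard errors at 100,000 patients on a 10-cycle horizon, and
  exact equality in deterministic limits (all probabilities 0 or 1).
* **Closed forms.** With recurrence off and constant hazard, the
  engine (start-of-cycle accrual mode) matches the geometric annuity
  `Σ (1−q)^{t−1}(1+r)^{−(t−1)}` with the cycle-1 month blend to 1e-9.
* **Structural invariants**, fuzzed over random valid configurations:
  row-stochastic transition matrices (1e-12), occupancy conservation
  (1e-9), monotone death occupancy, QALYs monotone in discount rate
  and recurrence probabilities, CEAC fractions a probability partition
  at every WTP, bit-identical reruns under fixed seeds.

Problem sizes used in the shipped test suite — 3,000 PSA iterations in
the acceptability checks, 30,000–100,000 microsimulation patients on
10-cycle horizons, 1,000 random triples for the dominance brute-force
cross-check — are the package's choices for a fast default suite; the
acceptance script runs the full 30,000-iteration PSA.

## Limitations

* The synthetic life table approximates 2014 US mortality only in its
  old-age ballpark; absolute lifetime estimates inherit that
  approximation.
* Constant annual recurrence probabilities with no re-treatment, no
  tunnel states and no cure; recurrence risks persist to the end of
  life, which likely overstates late recurrence.
* The PSA spread is a convention (20% relative), not an evidence-based
  standard error per parameter; conclusions that depend on the spread
  should be read from the 10%/30% robustness runs.
* The near-tie in QALYs between surgery and MWA at the base case means
  small parameter shifts flip the dominance conclusion; the NMB and
  CEAC outputs, which quantify that sensitivity, are the more robust
  summaries.
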