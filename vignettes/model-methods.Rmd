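---
title: "Model and methods: the cost of ruling out preeclampsia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the cost of ruling out preeclampsia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preecon)
```

## The decision problem

About 7% of pregnant women present with suspected preeclampsia — new
hypertension or proteinuria after 20 weeks of gestation without a confirmed
diagnosis. Under standard of care (SOC), clinicians decide between outpatient
follow-up and hospitalization on blood pressure and proteinuria alone, and a
large share of admissions later turn out to have been unnecessary. The serum
sFlt-1/PlGF ratio changes that decision: a ratio of 38 or below rules
preeclampsia out for the short term with high negative predictive value,
38–85 is indeterminate, and 85 or above supports the diagnosis.

`preecon` implements a cohort decision-tree cost model comparing SOC with and
without the ratio test from the Swiss healthcare-system perspective, plus a
five-year budget-impact projection, deterministic sensitivity analyses, and a
patient-level microsimulation used as an internal cross-check. It is an
expected-cost model: no time-to-event structure, a single pass from initial
consultation to delivery.

## Model structure

Each strategy distributes the cohort over five mutually exclusive management
branches after a universal initial consultation:

* **low** and **intermediate** outpatient follow-up (8 weeks, then an
  uncomplicated delivery),
* **intermediate after hospitalization** — admitted on suspicion, discharged
  without preeclampsia, followed up, then delivery,
* **suspected preeclampsia with birth** — admitted and hospitalized until
  delivery,
* **preeclampsia after ambulatory care** — preeclampsia manifesting during
  outpatient follow-up (a false-negative triage), ending in a
  hospitalization with birth.

The strategy cost is
$C = \sum_b n_b \, c_b + N\,(c_{\mathrm{init}}) + T$,
where $n_b$ and $c_b$ are branch size and per-patient cost,
$N = \lfloor 86{,}919 \times 0.07\rfloor = 6084$ is the cohort, and
$T = N \times 140.80$ EUR is the testing strategy's evaluation cost (zero for
SOC). The headline quantity is the per-patient difference (testing minus
SOC), −346.20 EUR in the base case.

### Counts mode and probability mode

The base case stores branch-level cohort counts and total costs directly,
because the recorded branch counts and the recorded percentages are not
mutually consistent (e.g. $0.36 \times 0.27 \times 6084 = 591$, while the
branch table records 583). `allocate_cohort()` therefore has two modes:

* **counts** — returns the configured integers; this reproduces the recorded
  strategy table exactly and is the default everywhere;
* **probability** — expected fractional counts from the admission cascade:
  per-stratum admission probabilities
  ($0.76 \times 0.02 + 0.11 \times 0.55 + 0.13 \times 0.65 = 0.1602$) for the
  testing arm, the 36% SOC admission rate (27% of whom stay until birth)
  otherwise. The remaining conditionals — preeclampsia among the admitted in
  the testing arm, preeclampsia among outpatients, and the low/intermediate
  split — are not recorded as rates anywhere, so they are derived once from
  the configured branch proportions of the same strategy. Probability mode
  drives the sensitivity analyses that move probabilities, and the
  microsimulation.

Cohort arithmetic is fractional internally; integers appear only at display,
rounded half-up.

### Per-patient costs and the component decomposition

Per-patient branch costs are the configured branch totals divided by branch
sizes, carried at full double precision (all shipped totals are integers and
therefore exact). Each per-patient cost is additionally decomposed into
`outpatient_care`, `hospitalization` and `birth` components, because the
sensitivity analyses need to scale hospitalization costs and to strip birth
costs. The decomposition is this model's own convention — only branch totals
are recorded — and is constrained to sum exactly to the per-patient cost:

* every pathway ending in delivery carries the blended no-preeclampsia birth
  cost (6298.50 EUR) as its `birth` component;
* the discharged-after-admission branch carries the mean cost of a
  suspected-preeclampsia stay without birth (6300 EUR) as `hospitalization`;
  the remainder is follow-up care — about 2 weeks of intermediate follow-up
  under SOC and 4 weeks under testing, which is how those defaults were
  chosen;
* the two preeclampsia branches book their DRG excess over the blended
  delivery cost as `hospitalization` (their admissions and deliveries are a
  single DRG episode).

The 6298.50 EUR blend is implied by the outpatient branches (per-patient cost
minus 8 weeks of follow-up: 6297.60 from the low branch, 6299.55 from the
intermediate branch; the midpoint is stored). The vaginal/C-section split
(5500 / 7895.50 at a one-third C-section share) is a synthetic calibration
that reproduces this blend; only the blend enters the model.

## Costing layer

The outpatient catalog holds one row per tariff item with per-setting costs
and a per-setting billable flag. The venipuncture fee (6.42 EUR) is
administered in the initial and low settings but excluded from their
per-consultation totals; only this rule reproduces the recorded totals
(259.64 EUR for low). Weekly costs divide the *full* administered per-visit
cost by the week count: $266.06 \times 6 / 8 = 199.545$ EUR/week for the low
setting. The intermediate per-consultation total (546.94 EUR) exceeds the sum
of its listed items by 17.64 EUR; the recorded total is authoritative and is
stored as an override. Inpatient costs enter as group means (not medians),
matching the cohort-expectation framing: the model needs expected spend, not
a typical case.

`bottom_up_branch_cost()` recomposes branch costs from these atoms as an
independent check. The testing strategy's low and intermediate branches
reconcile with the implied per-patient costs within 0.05%; the SOC
intermediate branch differs by 0.7% and the preeclampsia branches are not
reconstructable from the printed atoms (their implied costs embed partial
episodes). Discrepant branches are reported, never forced.

## Budget impact

Adoption is stored as absolute yearly counts (1217, 2600, 3650, 5000, 6084
women tested in years 1–5) because the recorded counts are not round
fractions of 6084. Year $y$ mixes per-patient costs at that uptake, and costs
are discounted by $(1+0.035)^{-(y-1)}$ — year 1 undiscounted, the only
convention that reproduces the recorded discounted SOC totals. The per-arm
cost columns of the report are undiscounted (mirroring the recorded layout);
the mixed total, the all-SOC counterfactual and their difference are
discounted. Mixing and discounting commute, so the difference is identical
either way; a test checks this at cent precision. Unrounded per-patient costs
(10,925.27 / 10,579.07 EUR) feed the projection; row-level agreement with the
recorded table is within 0.01%, and the cumulative five-year difference is
−5,867,442 EUR.

## Sensitivity analyses

One-way specifications scale a single parameter (±20% for hospitalization
and test costs and for the admission probabilities of the two upper strata;
−20%/+100% for the ≤38 stratum's 2% admission rate). Cost specifications are
evaluated in counts mode against the exact base case; probability
specifications re-allocate the cohort in probability mode and are compared
against the probability-mode base saving, so each entry isolates its own
parameter's effect. Entries sort by absolute deviation, ties broken by label.
`tornado_summary()` collapses to one bar per parameter (the larger absolute
deviation of its two variations), the conventional tornado reading; on the
base case the test-cost bar (28.16 EUR) is the shortest.

Retest scenarios add test determinations without shifting management:
universal retesting costs exactly one extra unit cost per woman
(346.20 − 140.80 = 205.40 EUR saving); 6.5% retesting of the low setting and
4× retesting of intermediate follow-up patients are priced the same way. The
recorded savings for the latter two scenarios (and for several one-way
variations and the birth-cost exclusion) are *not* reproducible from the
described parameter changes alone — they imply unstated management shifts —
so the package reports its own computed values and the test suite asserts
directions, not those magnitudes. Hooks for management shifts are deliberately
absent: a re-routing fraction would be a free parameter with nothing to pin
it down.

## Synthetic cohort and registry

`simulate_patients()` draws individual pregnancies through the same
conditional cascade probability mode uses: stratum from the prevalence
vector, admission per stratum (in the ≤38 stratum an admission is equated
with a severe blood-pressure reading above 160/110 mmHg, the model's only
admission trigger there), then the derived preeclampsia and follow-up splits,
and a delivery mode at the one-third C-section share. Costs are assigned
deterministically from the branch per-patient costs, so the simulated mean
cost converges to the probability-mode expectation by construction of the
draws — the cross-check validates the cascade wiring and the law-of-large
numbers behaviour, not the cost data. What the generator does *not* emulate:
gestational-age dynamics, continuous biomarker values, correlations between
costs and patient characteristics within a branch, or neonatal outcomes.
Passing tests therefore say nothing about those aspects of real data.

`simulate_registry()` emulates inpatient registry records. Each group's
length of stay and episode cost are drawn from a log-normal distribution
parameterized from the recorded (median, mean) pair: the median fixes the
location ($\mu = \log m$) and the mean/median ratio fixes the scale
($\sigma = \sqrt{2\log(\bar{x}/m)}$). A log-normal is the natural choice:
strictly positive, right-skewed like cost data, and exactly two moments are
recorded. A group whose mean were below its median would be rejected — that
shape is impossible for this family. Length of stay and cost are drawn
independently within a group; the recorded tables carry no joint
information.

`recover_parameters()` returns sample proportions (the maximum-likelihood
estimates) with exact Clopper–Pearson 95% intervals. The coverage test runs
50 replicates at n = 20,000 and verifies the ≥93% coverage claim as a
one-sided binomial hypothesis test at α = 0.001, the statistically correct
way to test a coverage property by simulation — comparing a 50-replicate
point estimate directly to the threshold would fail routinely from the
estimate's own ±3.6% noise.

## Numerical conventions and problem sizes

* EUR amounts are doubles; all shipped totals are integers and therefore
  exact. Display rounding is half-up (to cents in CSVs, whole EUR in
  summaries). Accounting identities are tested at cent precision.
* The recorded strategy-table difference cell (−2,106,301) disagrees by 1 EUR
  with its own printed totals (66,469,362 − 64,363,060 = 2,106,302); the
  model's unrounded value is −2,106,301.8 and tests allow that single euro.
* Random draws always run under an explicit seed in a private RNG stream;
  identical (configuration, n, seed) gives byte-identical output.
* Default check sizes: 200,000 patients per arm for the convergence check
  (3-standard-error agreement both arms), 100,000 registry records for
  moment matching (2% relative error on group means), 50 × 20,000 for
  coverage. These sizes make the statistical assertions sharp while keeping
  the full suite around five seconds.

## Known limitations

* The model is a single-cohort expected-cost tree: no discounting within the
  pregnancy, no resource constraints, no patient heterogeneity beyond the
  branch structure.
* Probability mode cannot reproduce the recorded branch integers exactly
  (the recorded counts and percentages conflict); counts mode exists
  precisely for exact reproduction, and the two modes are never mixed in one
  result.
* Neonatal care, anticoagulants and corticosteroids are outside the cost
  perspective, as in the base-case data.
* The component decomposition is a modelling convention; alternative
  decompositions would change the hospitalization-cost and birth-exclusion
  sensitivity results (but not the base case).
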