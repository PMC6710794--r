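# preecon

Health-economic evaluation of adding sFlt-1/PlGF ratio testing to standard
of care for pregnant women with suspected preeclampsia, from the Swiss
healthcare-system perspective.

Suspected preeclampsia — new hypertension/proteinuria after 20 weeks of
gestation — affects about 7% of pregnancies. Managed on blood pressure and
proteinuria alone, 36% of these women are admitted to hospital although only
a quarter of the admitted develop the disease. The sFlt-1/PlGF serum ratio
rules preeclampsia out short-term when ≤38, so most women can safely stay in
outpatient follow-up. `preecon` quantifies what that triage is worth to a
payer. It is aimed at health-economists and HTA analysts who want the model
as inspectable, configurable code rather than a spreadsheet.

## The model

A cohort decision tree distributes N = ⌊86,919 × 0.07⌋ = 6084 simulated
pregnancies over five management branches (low / intermediate outpatient
follow-up, admission with discharge, hospitalization until birth, and
preeclampsia after ambulatory care). Strategy cost is

  C = Σ_b n_b·c_b + N·c_init + T,

with branch sizes n_b, per-patient costs c_b, and testing cost
T = N × €140.80 (testing strategy only). On top of the tree:

* **budget impact** — five-year projection under an adoption schedule with
  3.5%/year discounting (year 1 undiscounted),
* **sensitivity** — one-way ±20% (and −20%/+100%) parameter variations and
  named scenarios (retesting, birth-cost exclusion), tornado-ready,
* **costing layer** — itemized Tarmed-style outpatient tariffs and DRG
  inpatient group means, with a bottom-up branch-cost reconstruction,
* **microsimulation** — patient-level draws through the same cascade, used
  as a convergence cross-check, plus a synthetic inpatient registry with
  moment-matched log-normal costs.

All parameters live in one YAML document (`inst/extdata/base_case.yaml`);
every numeric field carries a provenance entry, and a test enforces 100%
coverage. See the methods vignette (`vignettes/model-methods.Rmd`) for the
full model description.

## Worked example

```r
library(preecon)
cfg <- load_config()                 # shipped base case
validate_config(cfg)$ok              # TRUE

compare_strategies(cfg)
#> <pe_comparison> test - no_test (counts mode)
#>   delta total: EUR -2,106,302; per patient: EUR -346

strategy_cost(cfg, "test")
#> <pe_strategy_result> test (counts mode)
#>   medical costs: EUR 63,506,433; test costs: EUR 856,627
#>   overall: EUR 64,363,060 (EUR 10,579 per patient); hospitalized until birth: 822

run_budget_impact(cfg)
#> <pe_budget_impact> 5 years, discount 3.5%/year (counts mode)
#>   yearly differences (EUR): -421,330, -869,690, -1,179,624, -1,561,278, -1,835,520
#>   cumulative difference: EUR -5,867,442
```

Reading: testing every woman costs €856,627 but avoids enough unnecessary
hospitalization (822 vs 1160 women hospitalized until birth) to save €346
per patient — about €2.1M per year for the full cohort — and €5.87M
cumulatively over a five-year adoption ramp. `sensitivity_suite(cfg)` returns
the tornado table (hospitalization costs dominate; the test price itself has
the smallest bar), and

```r
summarize_patients(simulate_patients(cfg, "test", 50000, seed = 7), cfg$cohort_size)
#> <pe_sim_summary> n = 50000
#>   mean cost/patient: EUR 10597.69 (SE 9.19); initially hospitalized: 15.9%
```

cross-checks the deterministic expectation by microsimulation (the
probability-mode expectation lies within the standard error).

A command-line wrapper is included:

```sh
Rscript inst/scripts/preecon.R report --outdir out     # compare + bia + sensitivity
Rscript inst/scripts/preecon.R simulate --n 10000 --seed 1 --outdir out
```

Every run writes CSV results plus a JSON manifest (config digest, command,
seed) so any number can be reproduced.

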