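# nodulecea

Cost-effectiveness modelling of an autoantibody blood test (AABT) added to
CT surveillance for indeterminate pulmonary nodules (IPNs).

Patients with a 4–20 mm lung nodule face a malignancy risk too low for
immediate biopsy; UK guidance is CT surveillance at 3, 12 and 24 months. An
autoantibody test offers up-front triage: positives proceed to
multidisciplinary review, guided needle biopsy and surgery if malignancy is
confirmed; negatives lose nothing, since they follow the surveillance
pathway they would have received anyway. `nodulecea` is aimed at health
economists and methodologists who want that comparison as a tested,
reusable, scriptable model rather than a spreadsheet or a proprietary
decision-tree file.

## The model

A decision tree for the testing pathway feeds a monthly-cycle Markov cohort
model (states: undiagnosed benign/local/regional/distant, diagnosed
counterparts with months-since-diagnosis tunnels, disease-free, dead) run
from age 62 to age 100. Outcomes are discounted (3.5%/yr, half-cycle
corrected) lifetime costs (GBP 2016/17) and QALYs, compared via the
incremental cost-effectiveness ratio ICER = ΔC/ΔQ and net monetary benefit
NMB = Q·λ − C at λ = £20,000/QALY. Around the deterministic core sit:

- probabilistic sensitivity analysis with Beta / conjugate-count / HSROC
  joint sampling and common random numbers across strategies (`run_psa()`),
  cost-effectiveness acceptability curves (`ceac()`);
- threshold-price analysis exploiting cost linearity in the test price,
  closed form cross-checked by bisection (`threshold_price()`);
- expected value of perfect information and regression-based (GAM) partial
  EVPI per parameter group (`evpi_per_person()`, `evppi_regression()`).

Every published model input ships in a validated registry
(`ipn_parameters()`); the only unpublished input, the age-indexed all-cause
mortality table, is emulated by a calibrated Gompertz life table
(`gompertz_life_table()`, life expectancy 23 years at age 62) and can be
replaced by a real national life table via `load_life_table()`.

## Worked example

```r
library(nodulecea)

defs   <- ipn_parameters()          # published parameter registry
params <- draw_parameter_set(defs)  # base-case values
lt     <- gompertz_life_table()     # synthetic UK-like life table
cfg    <- scenario_config("A")      # AABT sensitivity 0.41, specificity 0.93

tab <- evaluate_strategies(params, c("surveillance", "aabt_B", "aabt_A"),
                           cfg, lt)
compare_strategies(tab, wtp = 20000)
#> # A tibble: 3 x 9
#>   strategy     cost  qaly cost_undisc qaly_undisc status  inc_cost inc_qaly  icer
#> 1 surveillance 2617. 10.7       2668.        16.0 frontier     NA    NA       NA
#> 2 aabt_B       2735. 10.7       2783.        16.1 frontier    117.    0.0558 2103.
#> 3 aabt_A       2796. 10.8       2843.        16.1 frontier     61.0   0.0255 2390.
```

Reading the output: surveillance alone costs £2,617 and yields 10.687
discounted QALYs per patient under the synthetic life table. Adding the
test under Scenario B buys 0.0558 extra QALYs for £117 (ICER ≈ £2,103/QALY);
moving on to Scenario A buys a further 0.0255 QALYs at ≈ £2,390/QALY. Both
sit far below the £20,000/QALY acceptance threshold, so Scenario A testing
is the preferred strategy — the published qualitative conclusion, reproduced
here end to end. Uncertainty and price analyses follow the same pattern:

```r
psa <- run_psa(defs, cfg, n_draws = 1000, seed = 1,
               strategies = c("surveillance", "aabt_B", "aabt_A"),
               life_table = lt)
plot_ceac(psa)                             # acceptability curves
threshold_price(params, cfg, lt)           # max price keeping NMB ahead
evpi_per_person(psa, seq(0, 50000, 2500))  # value-of-information curve
```

`run_analysis()` drives the same computations from a YAML/list
configuration and writes seed- and hash-stamped CSVs (`basecase`, `psa`,
`voi`, `threshold` commands).

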