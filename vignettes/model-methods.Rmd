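---
title: "Methods: a decision-tree + Markov model for autoantibody testing of indeterminate pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree + Markov model for autoantibody testing of indeterminate pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulecea)
```

## The decision problem

Indeterminate pulmonary nodules (IPNs, 4–20 mm) carry a malignancy risk that
is too low to justify immediate biopsy. UK practice is CT surveillance
("watchful waiting"): repeat scans at 3, 12 and 24 months looking for nodule
growth. An autoantibody blood test (AABT) offers a way to triage these
patients up front: test-positive patients go straight to multidisciplinary
team (MDT) review, guided needle biopsy and — if malignancy is confirmed —
surgery, while test-negative patients follow the surveillance schedule they
would have received anyway.

`nodulecea` implements the full economic comparison of **AABT + surveillance**
against **surveillance alone** for a cohort of 62-year-olds with IPNs:
a decision tree for the up-front testing pathway feeding a monthly-cycle
Markov cohort model run over a lifetime horizon, with quality-adjusted life
years (QALYs) and UK NHS costs (GBP, 2016/17) as outcomes.

## Model structure

### Health states

The cohort occupies the states: undiagnosed benign (with a latent
"growth observed since last scan" flag), undiagnosed malignant at local,
regional or distant stage, diagnosed benign, diagnosed local / regional /
distant cancer, disease-free, and dead. The diagnosed cancer states are
expanded into monthly *tunnel* sub-states tracking time since diagnosis, so
that year-banded excess mortality and the 5-year disease-free exit are exact
rather than approximated: diagnosed local and regional run 60 tunnel months
and then exit to disease-free; diagnosed distant runs 48 tunnel months and
then continues at the final (37–48 month) excess risk for life, reflecting
the assumption that distant-stage patients face a constant cancer mortality
risk for the rest of their lives.

### Transitions

All transition probabilities are monthly. The central disease dynamics are:

* undiagnosed local → regional and regional → distant progression at
  0.19224/month (derived by the original modellers from a maximum-likelihood
  exponential fit to observed nodule doubling times — the package provides
  `fit_exponential_rate_ml()` and `prob_from_rate()` so this calibration step
  is itself testable on synthetic data);
* undiagnosed malignant excess mortality of 0.02688/month in **all**
  undiagnosed malignant states, the constant-hazard equivalent of a
  36.7-month life expectancy with an untreated 2 cm nodule
  (`monthly_prob_from_mean_survival(36.7)`). We considered applying the
  year-banded distant-cancer rates to undiagnosed distant disease instead,
  but the 36.7-month basis describes the *whole* untreated course, so the
  flat rate is the consistent reading;
* diagnosed-cancer excess mortality by year since diagnosis
  (local 0.0106/0.0100/0.0090/0.0114; regional 0.0340/0.0296/0.0225/0.0155;
  distant 0.1255/0.0670/0.0589/0.0150). The year-5 band is not published for
  local/regional; we continue the year-4 value through months 49–60, the
  same continuation rule used for distant disease beyond month 48;
* benign nodule growth fires at 0.28 in the first model month and
  0.005/month thereafter, but is *acted on* only at the next scheduled scan
  (nodules are diagnosed following a CT scan), which the latent grown flag
  tracks;
* age-specific background mortality applies in every alive state as an
  independent competing risk.

Within a cycle, events compose in a fixed order — scheduled detection,
disease progression, cause-specific mortality, background mortality — so
each matrix row is an enumerable event tree (e.g. undiagnosed local →
regional is `0.19224 × (1 − 0.02688) × (1 − background)`); the test suite
checks rows against this enumeration and the whole trace against an
independent multinomial micro-simulation.

### Testing pathways

The AABT arm applies the test once at model entry (sensitivity/specificity
0.41/0.93 in Scenario A, 0.28/0.98 in Scenario B; £70 list price). Positives
incur MDT review (£111.99) and a guided needle biopsy (£948.92, mortality
29/31960, serious adverse events 230/31960 costing 0.2 utility for one
month); biopsy-confirmed malignancies go to surgery; false positives return
to surveillance (biopsy-benign patients remain under surveillance).

Scans at months 3, 12 and 24 cost £85.56 for everyone still under
surveillance. Growth in a benign nodule is detected with certainty and leads
to surgical biopsy (complication-weighted cost £3,327.85, mortality 0.005),
after which patients are diagnosed benign and — because imaging is not
repeated after an invasive procedure — receive no further scheduled scans.
Undiagnosed malignant nodules are detected with CT sensitivity 0.923 at
every scan (a config toggle defers detection to the second scan for users
who prefer to require an observed doubling first); detection triggers MDT,
needle biopsy and surgery into the diagnosed tunnel appropriate to the
attained stage. CT specificity 0.723 is applied to non-grown benign nodules
at each scan, generating false-positive needle biopsies; without this the
published CT specificity would play no role. After the 24-month scan,
undetected patients are discharged: benign nodules accrue no further costs
and undetected malignancies continue their natural history unobserved.

Surgery for a malignant nodule costs
`(1−0.084)·£7,713.03 + 0.084·£10,177.74 + (5/35)·£3,252 + (11/35)·£4,155.15 = £9,690.54`
in expectation (complication mix plus adjuvant radiotherapy/chemotherapy)
with 4.2% operative mortality; survivors enter the diagnosed tunnel of their
pre-surgical stage. The blanket rule "surgery follows any biopsy-confirmed
malignancy" is applied uniformly, including distant-stage detections.

### Outcomes

Utilities are age-banded population norms (0.810 to 64, 0.773 at 65–74,
0.703 from 75) for benign, diagnosed-benign and disease-free states, and
stage-specific cancer utilities (0.71/0.65/0.62) — capped by the age norm —
in malignant states, diagnosed or not (a toggle switches undiagnosed states
to the age norm; at base case this moves total QALYs by <0.01 because
undiagnosed occupancy is brief). A monthly cycle earns `utility / 12` QALYs.
Costs and QALYs are discounted at 3.5% per year, `(1.035)^(−t/12)` at month
`t`, with half-weights on the first and last time points (half-cycle
correction); event costs are charged undiscounted at entry (month 0) and at
their scan month otherwise. The lifetime horizon is operationalized as
age 100 (456 monthly cycles from age 62).

## Background mortality

The only model input not published is the age-indexed all-cause mortality
table. `gompertz_life_table()` generates a synthetic stand-in,
`qx = 1 − exp(−a·e^{b·age})` with `b = 0.10`/yr and `a = 1.483×10⁻⁵` chosen
by root-finding so that remaining life expectancy at 62 is 23.0 years —
UK-like values fixed once, before any model result was inspected. A real
national life table can be supplied as a two-column CSV through
`load_life_table()` (gaps interpolated, old ages Gompertz-extrapolated, both
with warnings); exact reproduction of published absolute costs and QALYs
should not be expected under the synthetic table, and the package's own
acceptance checks therefore test *incremental* quantities and orderings
under it.

## Parameter uncertainty

`ipn_parameters()` loads the registry of every input with its uncertainty
specification; `draw_parameter_set()` realizes it. Rules, in order of
preference:

* parameters published as event counts (7/74 prevalence, 29/31960 biopsy
  mortality, 230/31960 complications, 5/35 and 11/35 adjuvant proportions)
  are sampled `Beta(events, n − events)` — the exact conjugate form;
* parameters with a published range use the method of moments
  (`beta_from_moments()`) with `SE = (U − L)/(2×1.96)` (`se_from_range()`);
* parameters published with "±50%" bounds use `U = 1.5·base, L = 0.5·base`
  on the probability scale (a `pm50_on_rate` switch reinterprets the bounds
  on the underlying exponential rate; at these magnitudes the difference is
  negligible);
* CT accuracy is sampled *jointly* through the hierarchical summary ROC
  curve: specificity ~ Beta(moments of 0.7234, SE 0.0276), accuracy
  parameter Λ ~ Normal(3.156, 0.2296), shape β = −0.5362433 held constant,
  and sensitivity computed as
  `logit(sens) = Λ·e^{−β/2} − e^{−β}·logit(spec)` — the reading of the
  summary equation that reproduces the published operating point
  (0.923, 0.723) exactly;
* utilities carry no published uncertainty but demonstrably contributed to
  the original sensitivity analysis, so they are sampled Beta with SE 0.05,
  a typical magnitude for EQ-5D norms and small oncology samples; the −0.2
  biopsy-event decrement is fixed. The AABT operating points are scenario
  definitions, not uncertain parameters, and are held fixed;
* costs have no published uncertainty and are fixed.

`run_psa()` evaluates all strategies under a common parameter set per draw
(common random numbers), which is what makes incremental costs and QALYs —
and the three-way acceptability curve — coherent. The default 1,000 draws
match the published analysis; invalid draws would be resampled and counted,
never silently dropped.

## Economic evaluation

ICERs are computed from unrounded internals (`compute_icer()`), multi-way
comparisons use standard efficiency-frontier ordering with strict and
extended dominance (`compare_strategies()`), and net monetary benefit is
`QALYs × WTP − cost` at £20,000/QALY by default. Because every presenting
patient is tested exactly once at model entry, total AABT-arm cost is linear
in the test price with slope one, so the threshold price has the closed form
`p* = p0 + (ΔQ·WTP − ΔC(p0))`; `threshold_price()` verifies it against a
bisection on the full model and requires agreement to £0.01.

## Value of information

`evpi_per_person()` is the mean over draws of the best attainable NMB minus
the best strategy's mean NMB. Population scaling uses 50,000 incident
patients/year over a 10-year technology horizon discounted at 3.5%, with the
first yearly cohort undiscounted (the discounting convention is a documented
toggle of `population_multiplier()`; the sum runs t = 0…9 ≈ 8.61 years'
worth, ~430,000 patients). `evppi_regression()` implements
nonparametric-regression partial EVPI: each strategy's NMB is regressed on
the group's sampled values with an additive spline smoother (`mgcv::gam`,
basis dimension 4 per parameter, no interactions — the standard
generalized-additive-model practice at 1,000 draws), and
`EVPPI = mean(max fitted) − max(mean fitted)`, truncated to the feasible
interval `[0, EVPI]` (regression smoothing noise can otherwise push the
estimate above the perfect-information bound). Estimates
below twice their Monte-Carlo standard error are flagged `near_zero`.
Default groups: disease-related mortality rates, initial patient
characteristics (prevalence and stage mix), and utilities.

## Numerical and design choices

* Monthly tunnels (60/60/48 states) rather than yearly buckets: exact
  year-band switching and disease-free exit at the cost of a ~180-state
  space, which the engine handles by building only one cause-specific matrix
  per growth regime and rescaling it per age year (background mortality
  enters every row as an independent competing risk, so each age's matrix is
  an affine transformation of the cause-specific one — asserted against the
  direct builder in the tests).
* Row-stochasticity is enforced to 1e-9 at assembly; cohort mass
  conservation to 1e-9 at every cycle, including through scan events.
* MDT fees are charged on AABT positives and scan-detected malignancies;
  false-positive CT findings and benign growth referrals are costed as their
  biopsy pathway only.
* Ties in the acceptability curve are split evenly so probabilities sum to
  one at every willingness-to-pay.

## What the synthetic fixtures do and do not show

The synthetic life table reproduces the *level* of UK old-age mortality but
not its exact age profile; with it, absolute lifetime QALYs land within a
percent of published values but incremental QALYs run some 20–30% high,
consistent with the synthetic table's slightly optimistic survivor life
expectancy compounding the treated-vs-untreated survival gap. The
log-normal doubling-time generator reproduces the right-skewed shape of
observed volume-doubling-time data, not the observed values; it exists so
the exponential-rate calibration loop can be property-tested
(generate → fit → recover).

Two published findings are *not* reproduced under the printed uncertainty
specification, and the package reports them honestly rather than forcing
them: the probabilistic analysis here finds Scenario A's net benefit exceeds
both comparators in essentially every draw (the published analysis found
~90% at £20,000/QALY, implying an uncertainty source — plausibly sampled
AABT accuracy — that is not documented), and consequently the EVPI at
£20,000/QALY is zero here while the published figure reads ~£1M. The EVPI
curve's characteristic single peak does appear at the decision-switching
willingness-to-pay (~£2,000–3,000), where the acceptability curves cross.

## Problem sizes

The packaged analyses use the study's own sizes: 456 monthly cycles,
1,000 PSA draws, 50,000-individual micro-simulation checks, 10,000-draw
distribution checks for samplers. A full three-way 1,000-draw PSA runs in
about a minute and a half on one core; a single base case in well under a
second.
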