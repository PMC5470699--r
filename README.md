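# laipersist

Treatment persistence of long-acting injectable antipsychotics (LAAPs),
reconstructed from retail-pharmacy dispensing records.

Dispensing panels record pharmacy pickups, not treatment. `laipersist` turns
longitudinal prescription-pickup transactions into continuous-treatment
episodes with a **permissible-gap** rule: after a purchase of coverage
period *c* days per unit, *u* units, under grace period *g*, the next
purchase of the same drug must arrive within

    permissible gap = c · u + g

or the patient is deemed discontinued at the day the last supply ran out
(*t = d_last + c · u* — the grace period decides continuation but never
extends the time). Around that core the package provides:

* **Cohort selection** for panel data: pharmacy transmission-continuity
  filters (every-month rule for NL; ≤2 missing months, ≤1 per rolling 12,
  for BE), new-initiator washout (no same-drug purchase in the prior 365
  days), and country-specific patient-activity filters.
* **Episode construction** for the four main depot products (paliperidone
  palmitate once-monthly, risperidone microspheres, haloperidol decanoate,
  olanzapine pamoate) over a 13-month window, under four grace scenarios
  (base 28 d, sensitivity 60 d, product-specific lower bounds, 390-d upper
  bound) shipped as data, including the NL-specific 14-day coverage of
  olanzapine 405 mg.
* **Baseline and sequel classification**: prior treatment in the 90 days
  before index (prior depot / prior oral antipsychotic / none) and, for
  episodes shorter than ten months, the 90 days after discontinuation
  (restart / other depot / other oral / none).
* **Dose and combination-therapy metrics**: dose at start (respecting the
  PP1M loading scheme) and end, average dose per 28 days, monotherapy vs
  combined status and anticholinergic use at months 1 and 6.
* **Comparative statistics**: Kaplan–Meier curves, Cox proportional-hazards
  hazard ratios vs a reference drug (Efron ties; covariates gender,
  standardized start strength, co-medication), and a logistic model of
  restarting, all with 95% Wald intervals.
* **A synthetic dispensing-panel generator** (`simulate_lrx()`) with known
  ground truth — per-drug discontinuation hazards, restart probabilities,
  pharmacy-month transmission gaps — so the entire pipeline is testable
  without proprietary data.

## Worked example

Simulate a 2000-patient panel and run the full pipeline for one inclusion
period (the olanzapine 300 mg pack length must be chosen explicitly — the
record does not identify it):

```r
library(laipersist)

man <- run_pipeline(
  sim     = sim_config(n_patients = 2000, seed = 7),
  periods = list(main = study_config(olanzapine_300_days = 28)))
man
#> <run_manifest> seed 7 - 1 period(s)
#>   main: transactions_observed=36891, pharmacies_total=100,
#>   pharmacies_eligible=50, transactions_eligible_pharmacies=19026,
#>   initiators=1022, after_activity_filter=997, cohort=997
```

Half the pharmacies missed at least one monthly transmission (2% monthly
failure rate over a ~31-month horizon) and were excluded wholesale, as the
Dutch continuity rule requires; 1022 new initiators survived the washout and
997 the activity filter. The adjusted Cox comparison against PP1M:

```r
man$periods$main$cox
#> Cox PH hazard ratios vs pp1m (n = 997, events = 698)
#>                      term   hr   lo   hi        p
#>     haloperidol_decanoate 1.31 1.07 1.61 9.73e-03
#>        olanzapine_pamoate 1.58 1.11 2.23 9.99e-03
#>  risperidone_microspheres 1.58 1.32 1.87 3.10e-07
```

Hazard ratios above 1 mean faster discontinuation than the PP1M reference;
here the generator was configured with true ratios of 1.45, 1.36 and 1.59,
so the fitted values are within sampling noise of truth. The restart model
on the 569 eligible discontinuers:

```r
man$periods$main$restart
#> Restart odds ratios vs pp1m (n = 569)
#>                      term    or    lo    hi        p
#>     haloperidol_decanoate 0.461 0.268 0.791 0.004988
#>        olanzapine_pamoate 0.687 0.297 1.589 0.380705
#>  risperidone_microspheres 0.448 0.288 0.695 0.000343
```

Odds ratios below 1 mean those cohorts were less likely than PP1M starters
to pick the same drug up again within three months of stopping.
`man$periods$main$continuation` holds per-scenario continuation fractions
(after one injection, 6 and 12 months), and `run_pipeline(..., out_dir =)`
writes all report tables — demographics, continuation, hazard/odds ratios,
sequel classes, dose/co-medication summaries, KM curve points — as CSV plus
a JSON manifest of the filter-chain counts.

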