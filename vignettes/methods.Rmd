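---
title: "Measuring treatment persistence of depot antipsychotics from dispensing records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring treatment persistence of depot antipsychotics from dispensing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-acting injectable antipsychotics (LAAPs) are depot formulations dispensed
every two to four weeks. Whether a patient stays on such a treatment — their
*persistence* — is one of the strongest real-world predictors of relapse in
schizophrenia, and retail-pharmacy dispensing panels are one of the few data
sources in which persistence can be observed without influencing it. The
catch is that a dispensing record shows only pharmacy visits. Everything
else — when treatment actually stopped, whether a late refill is a pause or
the end, what the patient switched to — has to be reconstructed by
algorithm. `laipersist` implements that reconstruction as a tested pipeline
for four depot products: paliperidone palmitate once-monthly (PP1M),
risperidone microspheres, haloperidol decanoate, and olanzapine pamoate, in
the Dutch and Belgian retail-pharmacy settings.

Because real dispensing panels are proprietary, the package ships a
synthetic-data generator that emulates their structure with known ground
truth. Every downstream stage is validated against that truth and against
independent brute-force oracles; nothing in the package depends on access to
real data.

## The permissible-gap model

The core quantity is the *permissible gap*: the longest interval after a
purchase within which the next purchase of the same drug must occur for
treatment to count as continuous,

$$\text{gap} = c \cdot u + g,$$

where $c$ is the coverage period (days of treatment per dispensed unit of the
purchased strength), $u$ the number of units dispensed, and $g$ a grace
period absorbing refill-timing slack. Scanning a patient's purchases in
order, the episode survives while each inter-purchase interval is at most
the permissible gap of the purchase that opened it; supply never stockpiles
across purchases. The episode ends either by *interruption* (a later
purchase exists but came too late — it is not part of the episode) or by
*complete stop* (no later purchase in the window). In both cases the time to
discontinuation is

$$t = d_{\text{last}} + c \cdot u,$$

the day the last qualifying purchase's supply ran out. The grace period
decides *whether* the episode continues but never extends the reported time.
If the supply end reaches the end of the 13-month observation window the
patient is right-censored there instead.

Coverage periods follow the products' SmPCs: 28 days per unit for PP1M and
haloperidol decanoate, 14 for risperidone microspheres, and for olanzapine
pamoate 28 days at 210 mg and — reflecting observed Dutch refill behaviour —
14 days at 405 mg in the Netherlands versus 28 in Belgium. The 300 mg
strength can be prescribed on either a 2- or 4-week scheme and the record
does not say which; the package refuses to guess and requires an explicit
`olanzapine_300_days` choice, erroring otherwise.

Four grace scenarios are bundled as data (`grace_scenarios()`): a 28-day base
case motivated by the pharmacokinetics of the depot products, a 60-day
sensitivity, product-specific lower bounds (7 days for 28-day products, 3 for
14-day packs), and a 390-day upper bound under which no interruption can be
declared inside a 13-month window — only complete stops remain, which is why
the episode builder treats a complete stop as an event even when the
permissible gap would stretch past the window, as long as the supply itself
does not.

## Cohort selection

Eligibility mirrors how panel data must be cleaned before longitudinal
follow-up is meaningful:

* **Pharmacy continuity.** Dutch analyses keep only pharmacies that
  transmitted data every month of the horizon. Belgian analyses tolerate two
  missing months overall but at most one inside any 12 consecutive calendar
  months (the rolling window is interpreted as any 12 consecutive months, an
  open point in the source rules).
* **New initiators.** A patient enters a cohort at the first purchase of an
  index drug in the inclusion period with no purchase of the *same* drug in
  the preceding 365 days. A patient qualifying on two drugs contributes one
  record, at the earliest initiation.
* **Activity filters.** NL: at least one transaction of any drug within 90
  days after index (window closed at day 90). BE: drop patients with exactly
  one index transaction and fewer than three units of anything else in the
  prior year.

Month-based durations are fixed as day counts — 365-day washout, 395-day
(13-month) follow-up, 90-day pre/post windows, 300-day (ten-month) sequel
restriction, 28-day "month" blocks — because the source design never defines
a month's length and exact day counts make every boundary testable. All are
configurable in `study_config()`.

Baseline treatment in the 90 days before index is classified by priority
(any other depot → prior-LAAP; else any antipsychotic, ATC N5A → prior-other-AP;
else no-AP), and the same priority logic classifies the 90 days after a
computed discontinuation (index drug → restart; other depot; other oral
antipsychotic; none), restricted to episodes shorter than ten months. The
sequel window anchors at the computed supply end, not the last pharmacy
visit, since that is the day treatment is considered to have stopped.

## Statistics

Time to discontinuation is compared across drug cohorts with the
Kaplan–Meier product-limit estimator and a Cox proportional-hazards model
(via the `survival` package) adjusted for gender, drug strength at
initiation, and co-medication use; restarting within three months of
discontinuation is modelled by logistic regression with the same
covariates. Conventions the source design leaves open are fixed as follows:

* **Ties.** Day-granular refill data tie heavily; the Efron approximation is
  used (deterministic, more accurate than Breslow under heavy ties).
* **Intervals.** Two-sided Wald 95% confidence intervals, α = 0.05.
* **Strength encoding.** Raw milligrams are incomparable across products, so
  the start dose is divided by the drug's modal start dose, giving a
  dimensionless covariate equal to 1 for a typical starter.
* **Co-medication.** The month-1 combination flag (any non-index
  antipsychotic purchase in days 0–27).
* **Degeneracy.** Complete or quasi-separation in the logistic model and
  non-convergent Cox fits raise warnings carrying diagnostics; they are
  never returned silently.

"Continuation after one injection" admits two readings — the share of
patients with a second qualifying purchase (or censoring on first supply),
and KM survival at one coverage period — so the continuation table reports
both, labelled distinctly.

## The synthetic panel

`simulate_lrx()` emulates the structure of a national retail-pharmacy panel:
anonymised patients loyal to a single pharmacy, per-drug refill streams, and
a pharmacy × calendar-month transmission log whose failures delete the
affected transactions from the observed table (they happened but are
unobserved). Latent discontinuation times follow per-drug Weibull hazards
with shape 1 (exponential) by default, so true pairwise hazard ratios are
exactly the ratios of configured rates — the property the parameter-recovery
tests exploit. Refill intervals are coverage × units plus rounded Gaussian
jitter (SD 4 days by default), floored at 7 days. Restart behaviour draws a
per-drug Bernoulli flag and, when set, places the first repurchase uniformly
29–90 days after the supply end — beyond the base grace period, so a restart
is never mistaken for continuation under the base scenario (under the 60-day
sensitivity some restarts legitimately merge into the episode).

Default parameters are chosen to resemble a plausible two-country LAAP
panel: cohort mix ≈ 40/34/21/5% across PP1M/risperidone/haloperidol/
olanzapine, discontinuation rates of 0.0022–0.0035 per day (12-month
continuation roughly 28–45%), restart probabilities 0.22–0.35, prior-depot
history concentrated in the PP1M cohort (0.32 vs 0.02–0.03), 2% monthly
transmission failure, and a 50% uptake of the PP1M loading scheme (150 mg
day 0, 100 mg day 7). Prior-depot history is drawn from non-index depot
products (flupentixol, zuclopenthixol, bromperidol decanoate) so that each
simulated patient has exactly one qualifying initiation and the ground truth
stays unambiguous. These are conventions, not estimates of any particular
market; the generator deliberately does not try to reproduce published
national results, whose source data are proprietary.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: patients switching pharmacies mid-follow-up
(loyalty is 1 by default; an off-panel-visit knob exists to study the
underestimation bias leakage would cause), hospital dispensing, seasonal or
calendar effects, informative censoring (death, institutionalisation),
channel bias in prescribing, and dose-dependent discontinuation. Covariates
in the generator carry no effect on the hazard, so covariate-adjusted and
unadjusted fits estimate the same quantity in recovery tests.

## Numerical and design choices

* Same-day purchases of one strength merge by summing units; when two
  strengths are picked up on one day, the purchase providing the longer
  supply governs the gap and the end-dose, while all purchases count toward
  dose totals.
* Mid-episode strength changes apply each purchase's own coverage period to
  its gap.
* PP1M purchases within 14 days of index are flagged as the SmPC initiation
  scheme; the dose-at-start is the first injection after that window. Other
  products have no configured scheme.
* The average dose per 28 days divides total milligrams over the episode by
  the time to discontinuation (supply end); a switch divides by the
  last-purchase offset instead, since "observed time on medication" admits
  either reading.
* The median age band of a cohort is the band of the middle patient; with an
  even count the lower band is reported.
* Unsorted purchase input is sorted; purchases on or after day 395 are
  outside the retrieval window and ignored.

## Validation

The test suite checks, among other things: exact agreement of the gap scan
with a brute-force day-by-day supply/grace simulator over an exhaustive
enumeration of ≈10⁵ purchase patterns (all ≤4-purchase subsets of a weekly
200-day grid × 4 drugs × 4 scenarios × 2 countries); hand-computed
permissible gaps and discontinuation times for every tabulated
coverage/grace combination; monotonicity of 12-month continuation in the
grace period on a seeded cohort of 2000 generated patients, with exactly
zero interruption-mode discontinuations under the 390-day bound; recovery of
a true hazard ratio of 1.5 (two 2000-patient arms, 100 replicates, ≥93%
Wald-CI coverage required, pooled estimate within ±0.15) and of a true
restart odds ratio of 0.5 (restart probabilities 0.4 vs 0.25, same
replicate scheme), with the unadjusted odds ratio matching the 2×2
cross-product ratio to 10⁻⁶; and partition invariants (baseline, sequel and
month-6 classes each sum to their denominators) on every pipeline run.
Problem sizes — 2000-patient demo panels, 4000-patient recovery arms, 100
replicates — were chosen so the whole suite exercises realistic cohort sizes
while remaining comfortable to run routinely.

## Limitations

Beyond the generator's simplifications listed above: the pipeline estimates
*ambulatory* persistence only (a hospital stay looks like a gap); the
permissible-gap rule cannot distinguish a clinically intended switch from
loss to follow-up within the episode itself (the sequel classifier addresses
this separately); and the 300 mg olanzapine ambiguity means cohorts
containing that strength depend on an explicit analyst choice, which should
be reported alongside results.
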