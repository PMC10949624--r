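---
title: "Methods: a Markov cohort model for the cost of first-year non-surgical periodontal care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for the cost of first-year non-surgical periodontal care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioburden)
```

## The problem

Periodontitis is managed over a patient's lifetime, but the first year after
presentation — non-surgical periodontal treatment (NSPT, i.e. subgingival
instrumentation with or without systemic antibiotic adjuncts) followed by
quarterly recall — is where the care pathway is most standardised and where a
cost-of-illness estimate is most defensible. `perioburden` estimates the
national direct-medical-cost burden of that first year in specialist clinics,
from the provider's perspective, in a dual public/private system. It was
built around the Malaysian 2020 setting and ships that configuration as its
base case, but every input is data, not code: census count, prevalences,
utilisation fractions, visit rates, cost schedules, transition rows and the
exchange rate all live in a JSON/CSV configuration.

The pipeline has four stages, each usable on its own:

1. **Care-seeking cascade** (`epi_pipeline()`): from census and survey
   fractions to the number of treated patients per sector.
2. **Cost schedules** (`cost_schedule()` and friends): average direct medical
   cost per (sector, visit, periodontal state) cell.
3. **Transition derivation** (`build_matrices()` and the arm-summary
   operations): per-cycle 3x3 matrices over {stable, remission, unstable}.
4. **Markov cohort model and scaling** (`burden_pipeline()`): expected
   per-patient cost over 4 quarterly cycles, blended over treatment
   strategies, multiplied by treated counts, reported in MYR and USD.

A deterministic one-way sensitivity engine (`one_way_table()`) and a
synthetic-data module (`synthetic_truth()`, `generate_trial_summaries()`,
`microsimulate_cohort()`) complete the package.

## The cascade and its rounding conventions

With `b` the fraction of adults reporting a recent oral health problem, `c`
the adult census count, `f` the fraction of reporters who sought treatment,
and `s` the share of treatment seekers attributable to severe periodontitis,
the treated cohort is

$$ n = \big(\,(b \cdot c) \cdot f\,\big) \cdot s , $$

with **each stage rounded half-up to whole persons before the next**. This
convention is load-bearing: published national tables are built spreadsheet
fashion, stage by stage, and reproducing them exactly requires rounding at
the same points. The same applies to the sector split: the public share
`r_public / (r_public + r_private)` of the per-capita visit rates is rounded
to three decimals (one decimal in percent) *before* multiplying. With the
base-case inputs the unrounded share (0.79310) would give 66,618 public
patients; the rounded share (0.793) gives the published 66,609.

The share `s` may be supplied directly (the base case ships 17.0% with CI
16.2–17.9%) or derived as `d/(d+e)` from the severe-periodontitis and caries
prevalences, under the assumption that problem reporting is symptom-driven —
so moderate periodontitis, which is largely asymptomatic, is deliberately
excluded from the numerator.

Interval bounds are propagated **stage-wise by simultaneous substitution**:
the "lower" cascade substitutes every input's lower limit at once. Note that
a substituted bound is not always the smaller value — both visit rates at
their lower limits give a *larger* public composition (81.5% vs 79.3%) —
which is why `sector_counts` labels rows by which bound was substituted, not
by order.

`round_half_up()` is exported because base R's `round()` rounds half to
even; commercial rounding is what published person and money tables use.

## Cost schedules

Each (sector, visit, state) cell is the sum of procedure unit costs weighted
by the fraction of patients receiving each procedure
(`weighted_visit_cost()`), with unit costs restated to the price year by GDP
deflator ratios (`deflate_cost()`). The packaged base case ships the
resulting averages directly (procedure-level reconstruction is supported but
not needed to reproduce headline figures). Structure of the packaged
schedules, in 2020 MYR per patient:

* Visit 0 (initial assessment + cause-related therapy) is strategy-specific;
  patients enter unstable, so only the unstable cells enter the base case,
  blended by the strategy mix (default 80% NSPT only, 16% NSPT+AMOX+MET, 4%
  NSPT+AZ — i.e. 20% receive antibiotics, of whom 80% amoxycillin +
  metronidazole and 20% azithromycin).
* Recall visits 1–3 share identical cells; visit 4 differs because
  periodontal surgery is considered only at the fourth recall (its cost is
  embedded in the visit-4 unstable cell rather than modelled as an event).
* Sensitivity bounds: public cells are varied by ±20% (exact scaling,
  rounded to the cent); private bounds are independently elicited fee ranges
  and are **not** a fixed multiple of the average — `cost_range_variant()`
  treats the two sectors accordingly.

Money is carried as MYR doubles at full precision and rounded half-up to the
cent only at rendering; USD conversion (default 0.2382 USD/MYR, the 2020
average) happens at reporting time only.

## Transition derivation

States follow the clinical case definitions: stable = probing pocket depth
(PPD) ≤ 4 mm and bleeding on probing (BOP) < 10% of sites; remission =
pockets controlled but BOP ≥ 10%; unstable = PPD ≥ 5 mm. The model is
irreducible — no tooth-loss absorbing state, because tooth loss is rare
within the first treatment year.

**Unstable row, cycle 1** (3-month post-treatment outcomes): from trial-arm
summaries. The fraction with controlled pockets is estimated by a threshold
model on the arm's summary statistics,
$\Pr(\text{controlled}) = \Phi\!\big((4.5 - \bar{x}_{PPD})/s_{PPD}\big)$,
where the 0.5 mm offset reflects the integer banding of the definition
("4 mm and less" vs "5 mm and more"). The controlled mass splits between
stable and remission by a point indicator on the arm's mean BOP against the
10% threshold — the two outcomes are mutually exclusive, and with only
arm-level summaries available a sharper split is not identifiable. This
realisation is isolated in `state_proportions_from_summary()` so a
patient-level alternative can be swapped in. Control-arm proportions are
pooled by event counts; adjunct strategies are obtained by pooled relative
risks (`pooled_relative_risk()`, with Haldane–Anscombe continuity correction
when a pooled event count is zero) applied to the control row and
renormalised (`apply_rr()`).

**Stable and remission rows**: published 1-year probabilities converted
entry-wise to the 3-month cycle by the constant-rate formula
$p_{cycle} = 1 - (1-p_{annual})^{1/4}$ (`annual_to_cycle()`), then
renormalised to sum to 1. The exact multi-state conversion (a matrix root)
is deliberately rejected: it is not identifiable from row-wise published
annual probabilities, can produce negative entries, and the per-transition
formula is the one the surrounding literature uses. Probability-1 entries
pass through unchanged so degenerate rows (e.g. the identity) convert to
themselves.

**Cycle structure**: the cycle-1 unstable row is strategy-specific (adjunct
effects act at the initial instrumentation); cycles 2–4 share one
maintenance (re-instrumentation) row, since recall care is strategy-free in
the pathway. All matrices are otherwise fixed in time.

### The placeholder transition rows

The transition probabilities used in the original national analysis are not
published in machine-readable form. The packaged base case therefore ships
**synthetic placeholder rows**, labelled as such in `base_config.json`:
plausible first-year dynamics (roughly half of unstable patients stabilise
or enter remission after initial instrumentation, with modest adjunct
benefit, slower gains under maintenance re-instrumentation, and mostly
persistent stable/remission states annually). Consequences:

* The cascade, compositions, treated counts, cost schedules, sensitivity
  structure and all published *arithmetic* reproduce exactly — they do not
  depend on the matrices.
* The headline national burden is checked against the *envelope* implied by
  the cost schedule (blended public per-patient cost must lie between the
  all-stable hand sum 4,893.64 and the all-unstable hand sum 12,825.28 MYR),
  not against a point value. Users with access to the original matrices can
  transcribe them into `transition_spec` (mode `"rows"` or `"matrices"`) and
  obtain a point reproduction.
* A `per_patient_costs` calibration mode pins the blended per-patient sector
  costs (e.g. to published sector totals divided by counts) and bypasses the
  Markov costing; the sensitivity engine then exhibits the published
  proportional count scaling (+31.90% for the upper-bound cohort).

## The cohort model

`run_cohort()` left-multiplies the occupancy row vector through one matrix
per cycle, starting from (0, 0, 1). Costing
(`expected_patient_cost()`) attaches the strategy-specific unstable entry
cost at visit 0 and, for each recall visit k = 1..4, the state costs
weighted by the occupancy *after* the k-th transition — four recalls in
twelve months at three-month cycles. No discounting and no half-cycle
correction are applied: the horizon is one year and visits are discrete
events at cycle boundaries, so neither adjustment has anything to act on.

National scaling is linear: blended per-patient cost × treated count per
sector, summed, converted to USD. Treated counts enter as integers
(post-rounding from the cascade), so sector burdens are exact products.

## Sensitivity analysis

`one_way_table()` runs scenarios that each perturb exactly one parameter
group (asserted by config diff in the tests): excluding adjuncts (strategy
mix (1, 0, 0), which also switches every patient to the NSPT-only cycle-1
dynamics — the point of making cycle-1 matrices strategy-specific), the
lower/upper interval cascades for treated counts, and the low/high fee
schedules. Percent differences are reported against the base total and
printed to two decimals.

## The synthetic-data module

`synthetic_truth()` fixes a small trial landscape (four two-arm studies, two
per adjunct strategy, with low- and high-BOP pairs so every pooled state has
positive events, and equal arm sizes so population pooling matches equal-n
pooling of regenerated summaries), the implied true state proportions and
matrices, and a cost schedule drawn uniformly within the packaged bounds.
`generate_trial_summaries()` draws patient-level PPD from a normal law and
BOP from a beta law (precision 20) around the arm parameters and summarises
them; PPD and BOP are drawn independently — any real correlation between
pocket depth and bleeding is out of scope and a known limitation.
`microsimulate_cohort()` is the independent oracle for the cohort
expectation: it samples individual state paths and sums costs along them.

What passing tests show — and what they do not: parameter recovery (derived
rows within 0.03 of truth entry-wise at 5,000 patients per arm, averaged
over 10 seeds) and oracle agreement (relative gap below 0.5% at 200,000
simulated patients) validate the *estimators and the engine*, under the
generator's assumptions (normal PPD, beta BOP, independence, arms honestly
summarised). They cannot validate the threshold model against real
site-level clinical data, which the package never sees.

## Numerical choices and degenerate inputs

* Half-up rounding everywhere persons or cents are rounded
  (`round_half_up()`); tolerances 1e-9 for stochasticity checks, 1e-12 for
  the annual↔cycle round trip.
* `sd_ppd = 0` with the mean exactly at the 4.5 mm cut is a domain error
  (the indicator is undefined); off the cut it degenerates to a 0/1
  indicator.
* `annual_to_cycle(1, ·)` is a domain error (infinite rate); inside the row
  conversion a probability-1 entry carries through as 1.
* Zero pooled events trigger the continuity correction with a message; a
  control proportion that is still zero afterwards is an error.
* Relative-risk products above 1 are clamped before renormalisation.
* Sector counts are reconciled to tile the total within one person after
  independent rounding.
* Problem sizes in the default test run are chosen to make the checks sharp
  but quick: 100–250 random matrices for conservation properties, 20,000
  patients for microsimulation agreement in unit tests and 200,000 in the
  acceptance suite, 5,000 patients per arm over 10 seeds for recovery.

## Known limitations

* The packaged transition rows are placeholders (above); the headline burden
  from the base fixture is an envelope-checked illustration, not the
  published point estimate.
* BOP enters as a point indicator at arm level; with patient-level data a
  joint PPD/BOP model would be strictly better.
* Prevalences, utilisation and visit rates are fixed inputs; the package
  does not model their trends or uncertainty beyond the published CIs.
* One-way scenarios only; no probabilistic sensitivity analysis, no
  cost-effectiveness comparison, no QALYs, no indirect or societal costs,
  no surgical/rehabilitative pathway beyond the visit-4 unstable cost.
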