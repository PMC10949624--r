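# perioburden

Cost-of-illness estimation for first-year non-surgical periodontal
management in specialist clinics, built as a reusable R pipeline around a
3-state Markov cohort model. The packaged base case is the Malaysian 2020
setting — public and private sectors, provider perspective — but every
national input is configuration data, not code.

**Who it is for:** dental public-health analysts and health economists who
need a transparent, testable implementation of a care-seeking cascade, a
weighted per-visit cost schedule, trial-derived transition matrices, a
cohort model and a one-way sensitivity analysis — with every published
number reproducible from the shipped configuration.

## The model

Patients with periodontitis occupy one of three states — *stable*
(PPD ≤ 4 mm, BOP < 10%), *in remission* (PPD ≤ 4 mm, BOP ≥ 10%), *unstable*
(PPD ≥ 5 mm) — and everyone enters treatment unstable. The model runs four
3-month cycles (one year) with no absorbing state:

* **Cascade**: treated cohort `n = ((b·c)·f)·s`, each stage rounded half-up
  to whole persons (b = fraction reporting oral health problems, c = adult
  census, f = fraction of reporters who sought treatment, s =
  severe-periodontitis share of seekers), then split between sectors by
  per-capita visit rates.
* **Transitions**: first-cycle rows out of *unstable* derived from trial-arm
  summaries via a threshold model `Φ((4.5 − x̄)/s)` plus pooled relative
  risks; *stable*/*remission* rows from published annual probabilities via
  `p_cycle = 1 − (1 − p_annual)^(1/4)`, renormalised.
* **Costing**: expected per-patient cost = strategy-specific entry cost +
  Σₖ Σ_state occupancy × cost(sector, visit k, state); no discounting over
  the one-year horizon. National burden = per-patient × treated counts,
  reported in MYR 2020 and USD (0.2382 USD/MYR).
* **Sensitivity**: one-way scenarios (exclude adjuncts, count bounds, fee
  bounds), each perturbing exactly one parameter group.

The transition probabilities used in the original national analysis are not
published in machine-readable form; the shipped configuration carries
documented *synthetic placeholder* rows, and the headline burden is checked
against the cost-schedule envelope rather than a point value. See the
methods vignette (`vignettes/perioburden-methods.Rmd`).

## Worked example

```r
library(perioburden)

cfg <- base_config()
res <- burden_pipeline(cfg)

res$epi$sectors[res$epi$sectors$bound == "point", ]
#>   bound composition_public composition_private treated_public treated_private treated_total
#> 1 point              0.793               0.207          66609           17387         83996

res$report
#> National burden of first-year non-surgical periodontal management
#>   public      66609 patients x MYR     7,699.40 = MYR     512,849,377.60
#>   private     17387 patients x MYR    13,232.74 = MYR     230,077,582.83
#>   total    MYR 742,926,960.43 (USD 176,965,201.98 at 0.2382 USD/MYR)
```

Reading: of 11,975,843 adults estimated to have periodontitis, 83,996 (0.7%)
sought treatment; 79.3% of them used the public sector (66,609 patients).
Under the placeholder dynamics the blended first-year cost is MYR 7,699.40
per public patient (inside the hand-checkable envelope 4,893.64–12,825.28
spanned by the all-stable and all-unstable paths), giving a national total
of MYR 743 million. The sensitivity table:

```r
one_way_table(cfg, base_scenarios())
#>    id                                                label treated_public ... pct_diff
#>  base                                            Base case          66609 ...   +0.00%
#>     a                          Exclude the use of adjuncts          66609 ...   +0.37%
#>     b Lower limit of the proportion who received treatment          51768 ...  -25.42%
#>     c Upper limit of the proportion who received treatment          85920 ...  +31.96%
#>     d                     Lower limit of the treatment fee          66609 ...  -32.80%
#>     e                     Upper limit of the treatment fee          66609 ...  +33.02%
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/perioburden.R` (subcommands `epi`, `cost`, `transitions`,
`burden`, `sensitivity`, `synth`).

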