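{
  "description": "Base-case model configuration: 2020 national economic burden of first-year non-surgical periodontal management in Malaysian specialist clinics.",
  "census_adults": 24692460,
  "prevalence": {
    "all": {"point": 0.485, "lower": 0.460, "upper": 0.512},
    "moderate": {"point": 0.303, "lower": 0.290, "upper": 0.316},
    "severe": {"point": 0.182, "lower": 0.170, "upper": 0.196}
  },
  "utilisation": {
    "b": {"point": 0.087, "lower": 0.079, "upper": 0.095},
    "f": {"point": 0.230, "lower": 0.201, "upper": 0.262},
    "perio_share": {"point": 0.170, "lower": 0.162, "upper": 0.179},
    "visit_rate_public": {"point": 0.23, "lower": 0.22, "upper": 0.25},
    "visit_rate_private": {"point": 0.06, "lower": 0.05, "upper": 0.07}
  },
  "strategy_mix": {"NSPT_only": 0.80, "NSPT_AMOX_MET": 0.16, "NSPT_AZ": 0.04},
  "cost_schedule_files": {
    "public": "cost_schedule_public.csv",
    "private": "cost_schedule_private.csv"
  },
  "transition_spec": {
    "mode": "rows",
    "note": "SYNTHETIC placeholder transition rows: the transition probabilities actually used in the original analysis are not published in machine-readable form, so these rows are plausible stand-ins documented in the package vignette. Replace them with transcribed values to reproduce the published headline burden.",
    "stable_row_annual": [0.70, 0.20, 0.10],
    "remission_row_annual": [0.30, 0.50, 0.20],
    "unstable_cycle1_rows": {
      "NSPT_only": [0.45, 0.25, 0.30],
      "NSPT_AMOX_MET": [0.50, 0.25, 0.25],
      "NSPT_AZ": [0.48, 0.25, 0.27]
    },
    "unstable_maintenance_row": [0.35, 0.25, 0.40]
  },
  "cycle_length_months": 3,
  "n_cycles": 4,
  "exchange_rate_usd_per_myr": 0.2382,
  "price_year": 2020
}
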