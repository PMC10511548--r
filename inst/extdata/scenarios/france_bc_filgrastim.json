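{
  "meta": {
    "id": "france_bc_filgrastim",
    "country": "France",
    "cancer": "BC",
    "agent": "filgrastim",
    "provenance": {
      "clinical": "paper",
      "utilities": "paper",
      "mortality": "paper",
      "cohort": "fixture",
      "life_table": "synthetic",
      "discount": "fixture"
    }
  },
  "agent": "filgrastim",
  "cohort": {
    "cancer": "BC",
    "entry_age": 50,
    "sex_mix": 1,
    "n_cycles": 6,
    "cycle_length_days": 21,
    "cure_horizon_years": 20
  },
  "clinical": {
    "baseline_fn_risk": 0.158,
    "rr_later_cycles": 0.21,
    "rr_history": 9.09,
    "rr_gcsf": 0.42,
    "p_low_rdi_no_fn": 0.309,
    "p_low_rdi_fn": 0.488,
    "rdi_threshold_pct": 85
  },
  "utilities": {
    "u_chemo": 0.55,
    "u_fn_hosp": 0.33,
    "u_post_year1": 0.66,
    "u_post_later": 0.86
  },
  "mortality": {
    "cancer_annual_mortality": 0.03,
    "fn_case_fatality": 0.056,
    "hr_low_rdi": 1.002
  },
  "costs": {
    "fn_hospitalisation_cost": 6842.31793656453,
    "los_days": 6,
    "patient_weight_kg": 70,
    "drug_unit_price": 21.9883946923342,
    "doses_per_cycle": 5,
    "provenance": "calibrated",
    "gcsf_cost_per_cycle": null,
    "units_per_dose": null
  },
  "discount_rate_costs": 0.025,
  "discount_rate_effects": 0.025,
  "life_table": {
    "type": "gompertz",
    "a": 2.1e-05,
    "b": 0.1,
    "female_scale": 0.5,
    "terminal_age": 110
  },
  "wtp_grid": [0, 10000, 20000, 30000, 40000, 50000, 75000, 100000],
  "psa_iterations": 1000,
  "seed": 1,
  "psa": [
    {
      "name": "baseline_fn_risk",
      "low": 0.1,
      "high": 0.2,
      "family": "beta"
    },
    {
      "name": "rr_later_cycles",
      "low": 0.16,
      "high": 0.29,
      "family": "lognormal"
    },
    {
      "name": "rr_history",
      "low": 6.19,
      "high": 13.35,
      "family": "lognormal"
    },
    {
      "name": "rr_gcsf",
      "low": 0.3,
      "high": 0.57,
      "family": "lognormal"
    },
    {
      "name": "p_low_rdi_no_fn",
      "low": 0.278,
      "high": 0.34,
      "family": "beta"
    },
    {
      "name": "p_low_rdi_fn",
      "low": 0.371,
      "high": 0.649,
      "family": "beta"
    },
    {
      "name": "u_chemo",
      "low": 0.5,
      "high": 0.61,
      "family": "beta"
    },
    {
      "name": "u_fn_hosp",
      "low": 0.27,
      "high": 0.4,
      "family": "beta"
    },
    {
      "name": "u_post_year1",
      "low": 0.59,
      "high": 0.73,
      "family": "beta"
    },
    {
      "name": "u_post_later",
      "low": 0.77,
      "high": 0.95,
      "family": "beta"
    },
    {
      "name": "cancer_annual_mortality",
      "low": 0.027,
      "high": 0.033,
      "family": "beta"
    },
    {
      "name": "fn_case_fatality",
      "low": 0.048,
      "high": 0.063,
      "family": "beta"
    },
    {
      "name": "hr_low_rdi",
      "low": 0.657,
      "high": 1.527,
      "family": "lognormal"
    }
  ],
  "owsa": [
    {
      "name": "gcsf_cost_per_cycle",
      "low": 175.907157538673,
      "high": 263.86073630801,
      "family": "fixed"
    },
    {
      "name": "fn_hospitalisation_cost",
      "low": 5473.85434925163,
      "high": 8210.78152387744,
      "family": "fixed"
    },
    {
      "name": "los_days",
      "low": 4,
      "high": 10,
      "family": "fixed"
    },
    {
      "name": "patient_weight_kg",
      "low": 60,
      "high": 90,
      "family": "fixed"
    },
    {
      "name": "discount_rate",
      "low": 0,
      "high": 0.05,
      "family": "fixed"
    }
  ]
}
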