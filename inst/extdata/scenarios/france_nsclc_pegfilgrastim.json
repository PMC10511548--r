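{
  "meta": {
    "id": "france_nsclc_pegfilgrastim",
    "country": "France",
    "cancer": "NSCLC",
    "agent": "pegfilgrastim",
    "provenance": {
      "clinical": "paper",
      "utilities": "paper",
      "mortality": "paper",
      "cohort": "fixture",
      "life_table": "synthetic",
      "discount": "fixture"
    }
  },
  "agent": "pegfilgrastim",
  "cohort": {
    "cancer": "NSCLC",
    "entry_age": 65,
    "sex_mix": 0.35,
    "n_cycles": 6,
    "cycle_length_days": 21,
    "cure_horizon_years": 20
  },
  "clinical": {
    "baseline_fn_risk": 0.18,
    "rr_later_cycles": 0.21,
    "rr_history": 9.09,
    "rr_gcsf": 0.25,
    "p_low_rdi_no_fn": 0.25,
    "p_low_rdi_fn": 0.383,
    "rdi_threshold_pct": 85
  },
  "utilities": {
    "u_chemo": 0.57,
    "u_fn_hosp": 0.33,
    "u_post_year1": 0.72,
    "u_post_later": 0.69
  },
  "mortality": {
    "cancer_annual_mortality": 0.06,
    "fn_case_fatality": 0.112,
    "hr_low_rdi": 2.004
  },
  "costs": {
    "fn_hospitalisation_cost": 10741.7375454044,
    "los_days": 6,
    "patient_weight_kg": 70,
    "drug_unit_price": 349.089392743249,
    "doses_per_cycle": 1,
    "provenance": "calibrated",
    "gcsf_cost_per_cycle": null,
    "units_per_dose": 1
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
      "low": 0.178571428571429,
      "high": 0.339285714285714,
      "family": "lognormal"
    },
    {
      "name": "p_low_rdi_no_fn",
      "low": 0.225,
      "high": 0.275,
      "family": "beta"
    },
    {
      "name": "p_low_rdi_fn",
      "low": 0.345,
      "high": 0.421,
      "family": "beta"
    },
    {
      "name": "u_chemo",
      "low": 0.51,
      "high": 0.63,
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
      "low": 0.65,
      "high": 0.79,
      "family": "beta"
    },
    {
      "name": "u_post_later",
      "low": 0.62,
      "high": 0.76,
      "family": "beta"
    },
    {
      "name": "cancer_annual_mortality",
      "low": 0.054,
      "high": 0.066,
      "family": "beta"
    },
    {
      "name": "fn_case_fatality",
      "low": 0.101,
      "high": 0.123,
      "family": "beta"
    },
    {
      "name": "hr_low_rdi",
      "low": 1.159,
      "high": 3.463,
      "family": "lognormal"
    }
  ],
  "owsa": [
    {
      "name": "gcsf_cost_per_cycle",
      "low": 279.271514194599,
      "high": 418.907271291898,
      "family": "fixed"
    },
    {
      "name": "fn_hospitalisation_cost",
      "low": 8593.39003632353,
      "high": 12890.0850544853,
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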