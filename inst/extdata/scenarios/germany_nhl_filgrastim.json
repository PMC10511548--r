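{
  "meta": {
    "id": "germany_nhl_filgrastim",
    "country": "Germany",
    "cancer": "NHL",
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
    "cancer": "NHL",
    "entry_age": 60,
    "sex_mix": 0.45,
    "n_cycles": 6,
    "cycle_length_days": 21,
    "cure_horizon_years": 20
  },
  "clinical": {
    "baseline_fn_risk": 0.18,
    "rr_later_cycles": 0.21,
    "rr_history": 9.09,
    "rr_gcsf": 0.42,
    "p_low_rdi_no_fn": 0.408,
    "p_low_rdi_fn": 0.706,
    "rdi_threshold_pct": 90
  },
  "utilities": {
    "u_chemo": 0.61,
    "u_fn_hosp": 0.33,
    "u_post_year1": 0.79,
    "u_post_later": 0.89
  },
  "mortality": {
    "cancer_annual_mortality": 0.0652,
    "fn_case_fatality": 0.058,
    "hr_low_rdi": 2.08
  },
  "costs": {
    "fn_hospitalisation_cost": 4859.53542860322,
    "los_days": 6,
    "patient_weight_kg": 70,
    "drug_unit_price": 57.6135811814997,
    "doses_per_cycle": 5,
    "provenance": "calibrated",
    "gcsf_cost_per_cycle": null,
    "units_per_dose": null
  },
  "discount_rate_costs": 0.03,
  "discount_rate_effects": 0.03,
  "life_table": {
    "type": "gompertz",
    "a": 2.4e-05,
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
      "low": 0.367,
      "high": 0.449,
      "family": "beta"
    },
    {
      "name": "p_low_rdi_fn",
      "low": 0.635,
      "high": 0.777,
      "family": "beta"
    },
    {
      "name": "u_chemo",
      "low": 0.49,
      "high": 0.73,
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
      "low": 0.62,
      "high": 0.92,
      "family": "beta"
    },
    {
      "name": "u_post_later",
      "low": 0.79,
      "high": 0.96,
      "family": "beta"
    },
    {
      "name": "cancer_annual_mortality",
      "low": 0.0587,
      "high": 0.0717,
      "family": "beta"
    },
    {
      "name": "fn_case_fatality",
      "low": 0,
      "high": 0.089,
      "family": "beta"
    },
    {
      "name": "hr_low_rdi",
      "low": 1.19,
      "high": 3.7,
      "family": "lognormal"
    }
  ],
  "owsa": [
    {
      "name": "gcsf_cost_per_cycle",
      "low": 460.908649451997,
      "high": 691.362974177996,
      "family": "fixed"
    },
    {
      "name": "fn_hospitalisation_cost",
      "low": 3887.62834288258,
      "high": 5831.44251432387,
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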