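{
  "format": "psorpath-scenario",
  "currency": "AUD-2020",
  "notes": [
    "Costs as of 18 September 2020; health-system cost per dispense, net of the AUD 41.00 patient co-payment.",
    "Ustekinumab priced as 45 mg dispense, dosage suitable for an 85 kg patient.",
    "doses_per_dispense reflects PBS maximum quantities: 2 x 40 mg adalimumab, 4 x 50 mg etanercept, 2 x 80 mg ixekizumab; all others one dose per dispense.",
    "Week-0 loading of adalimumab (80 mg) and ixekizumab (160 mg) consumes two dispense units.",
    "Utilities per year, time trade-off: PASI 16.5 (<PASI75) and PASI 4.1 (PASI75 response)."
  ],
  "sequencing_rule": "base",
  "timeline": {
    "cycle_weeks": 12,
    "horizon_weeks": 96,
    "maintenance_review_interval_weeks": 24,
    "weeks_per_year": 52,
    "annual_discount_rate": 0
  },
  "monitoring": {
    "visit_induction": 113,
    "visit_maintenance": 75,
    "investigations_induction": 738,
    "investigations_maintenance": 80
  },
  "bsc": {
    "cyclosporine_induction": 2360,
    "cyclosporine_maintenance": 5644,
    "foam_induction": 128,
    "foam_maintenance": 256
  },
  "utilities": {
    "u_uncontrolled": 0.64,
    "u_controlled": 0.89,
    "sd_uncontrolled": 0.49,
    "sd_controlled": 0.11
  },
  "drugs": [
    {
      "name": "adalimumab",
      "cost_per_dispense": 1132,
      "doses_per_dispense": 2,
      "loading_dose_weeks": [0, 1],
      "loading_dose_units": [2, 1],
      "steady_interval_weeks": 2,
      "p_induction": 0.695,
      "p_induction_ci": [0.660, 0.726],
      "p_maintenance": 0.671,
      "p_maintenance_ci": [0.529, 0.787]
    },
    {
      "name": "etanercept",
      "cost_per_dispense": 1026,
      "doses_per_dispense": 4,
      "loading_dose_weeks": [0],
      "loading_dose_units": [1],
      "steady_interval_weeks": 1,
      "p_induction": 0.401,
      "p_induction_ci": [0.354, 0.451],
      "p_maintenance": 0.555,
      "p_maintenance_ci": [0.501, 0.609]
    },
    {
      "name": "guselkumab",
      "cost_per_dispense": 3771,
      "doses_per_dispense": 1,
      "loading_dose_weeks": [0, 4],
      "loading_dose_units": [1, 1],
      "steady_interval_weeks": 8,
      "p_induction": 0.868,
      "p_induction_ci": [0.838, 0.894],
      "p_maintenance": 0.882,
      "p_maintenance_ci": [0.846, 0.911]
    },
    {
      "name": "ixekizumab",
      "cost_per_dispense": 3396,
      "doses_per_dispense": 2,
      "loading_dose_weeks": [0, 2, 4, 6, 8, 10, 12],
      "loading_dose_units": [2, 1, 1, 1, 1, 1, 1],
      "steady_interval_weeks": 4,
      "p_induction": 0.888,
      "p_induction_ci": [0.865, 0.909],
      "p_maintenance": 0.850,
      "p_maintenance_ci": [0.792, 0.894]
    },
    {
      "name": "risankizumab",
      "cost_per_dispense": 5375,
      "doses_per_dispense": 1,
      "loading_dose_weeks": [0, 4],
      "loading_dose_units": [1, 1],
      "steady_interval_weeks": 12,
      "p_induction": 0.892,
      "p_induction_ci": [0.869, 0.913],
      "p_maintenance": 0.901,
      "p_maintenance_ci": [0.863, 0.929]
    },
    {
      "name": "secukinumab",
      "cost_per_dispense": 1440,
      "doses_per_dispense": 1,
      "loading_dose_weeks": [0, 1, 2, 3, 4],
      "loading_dose_units": [1, 1, 1, 1, 1],
      "steady_interval_weeks": 4,
      "p_induction": 0.831,
      "p_induction_ci": [0.802, 0.857],
      "p_maintenance": 0.886,
      "p_maintenance_ci": [0.806, 0.936]
    },
    {
      "name": "tildrakizumab",
      "cost_per_dispense": 3246,
      "doses_per_dispense": 1,
      "loading_dose_weeks": [0, 4],
      "loading_dose_units": [1, 1],
      "steady_interval_weeks": 12,
      "p_induction": 0.629,
      "p_induction_ci": [0.573, 0.684],
      "p_maintenance": 0.878,
      "p_maintenance_ci": [0.843, 0.914]
    },
    {
      "name": "ustekinumab",
      "cost_per_dispense": 3910,
      "doses_per_dispense": 1,
      "loading_dose_weeks": [0, 4],
      "loading_dose_units": [1, 1],
      "steady_interval_weeks": 12,
      "p_induction": 0.697,
      "p_induction_ci": [0.663, 0.731],
      "p_maintenance": 0.725,
      "p_maintenance_ci": [0.659, 0.782]
    }
  ]
}
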