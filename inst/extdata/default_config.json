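{
  "cohort_size": 357903,
  "p_screened": 0.9556,
  "incidence": {
    "point": 0.0001,
    "dist": { "family": "beta", "a": 6.57, "b": 53000 }
  },
  "p_accept_treatment": 0.99,
  "smn2_copy_probs": {
    "point": [0.48, 0.35, 0.17],
    "dist": { "family": "dirichlet", "alpha": [18, 13, 6] }
  },
  "p_symptomatic_2copy": {
    "point": 0.14,
    "dist": { "family": "beta", "a": 0.177, "b": 1.09 }
  },
  "p_false_negative_given_sma": 0.05,
  "p_bridge_preterm_ab": 0.05,
  "p_bridge_symptomatic": 0.99,
  "p_quebec": 0.23,
  "p_quebec_4copy_treated": 0.60,
  "quebec_4copy_drug_split": { "risdiplam": 0.80, "nusinersen": 0.20 },
  "clinical_type_probs": { "type1": 0.60, "type2": 0.25, "type3": 0.15 },
  "clinical_treatment_splits": {
    "type1": { "OA": 1.0 },
    "type2": { "OA": 0.50, "nusinersen": 0.25, "risdiplam": 0.25 },
    "type3": { "nusinersen": 0.50, "risdiplam": 0.50 }
  },
  "prices": {
    "screening_dbs": {
      "point": 10.76,
      "dist": { "family": "gamma", "shape": 3.07, "scale": 3.50 }
    },
    "ddpcr": 250,
    "nusinersen_per_dose": 118000,
    "oa_per_dose": 2910500,
    "risdiplam_per_mg": 193.97,
    "risdiplam_annual_under2": 93456,
    "risdiplam_annual_2plus": 354000
  },
  "state_costs_monthly": {
    "E": { "point": 15508, "dist": { "family": "gamma", "shape": 44.4, "scale": 349 } },
    "D": { "point": 7758,  "dist": { "family": "gamma", "shape": 44.4, "scale": 174 } },
    "C": { "point": 6906,  "dist": { "family": "gamma", "shape": 44.4, "scale": 155 } },
    "B": { "point": 3723,  "dist": { "family": "gamma", "shape": 44.4, "scale": 83.8 } },
    "A": { "point": 16.67, "dist": { "family": "gamma", "shape": 44.4, "scale": 0.375 } }
  },
  "cost_component_shares": {
    "E": { "health_system": 0.55, "out_of_pocket": 0.15, "indirect": 0.30 },
    "D": { "health_system": 0.55, "out_of_pocket": 0.15, "indirect": 0.30 },
    "C": { "health_system": 0.55, "out_of_pocket": 0.15, "indirect": 0.30 },
    "B": { "health_system": 0.55, "out_of_pocket": 0.15, "indirect": 0.30 },
    "A": { "health_system": 1.0,  "out_of_pocket": 0.0,  "indirect": 0.0 }
  },
  "state_utilities_annual": {
    "E": { "point": 0.00, "dist": { "family": "one_minus_gamma", "shape": 21700, "scale": 4.61e-05 } },
    "D": { "point": 0.32, "dist": { "family": "one_minus_gamma", "shape": 2180,  "scale": 4.46e-04 } },
    "C": { "point": 0.46, "dist": { "family": "one_minus_gamma", "shape": 2520,  "scale": 3.82e-04 } },
    "B": { "point": 0.65, "dist": { "family": "one_minus_gamma", "shape": 2920,  "scale": 3.24e-04 } },
    "A_under18": { "point": 0.92,  "dist": { "family": "one_minus_gamma", "shape": 8520, "scale": 1.08e-04 } },
    "A_18plus":  { "point": 0.864, "dist": { "family": "one_minus_gamma", "shape": 8610, "scale": 1.08e-04 } }
  },
  "econ": {
    "discount_annual": 0.015,
    "cycle_months": 1,
    "horizon_cycles": 960,
    "wtp_grid": [1000, 10000, 50000]
  },
  "entry": {
    "nbs_age_months": 1,
    "type1_age_months": 3.9,
    "type2_age_months": 52.8,
    "type3_age_months": 106.8,
    "type3_walking_frac": 0.76
  }
}
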