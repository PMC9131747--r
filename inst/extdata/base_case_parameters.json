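{
  "schema_version": "1.0",
  "incidence_per_100k": {
    "50-54": {
      "female": 89.6626,
      "male": 81.0559
    },
    "55-59": {
      "female": 112.4574,
      "male": 162.0833
    },
    "60-64": {
      "female": 154.6871,
      "male": 256.0943
    },
    "65-69": {
      "female": 190.2521,
      "male": 373.6808
    },
    "70-74": {
      "female": 242.631,
      "male": 498.0681
    }
  },
  "rr_20py": 2.84,
  "rr_30py": 3.87,
  "detect_stage_ldct": {
    "CIS": 0.037,
    "StageI": 0.6852,
    "StageII": 0.037,
    "StageIII": 0.1852,
    "StageIV": 0.0556
  },
  "detect_stage_ldct_msc": {
    "CIS": 0,
    "StageI": 0.5441,
    "StageII": 0.057,
    "StageIII": 0.1195,
    "StageIV": 0.2794
  },
  "sens_ldct": 0.79,
  "spec_ldct": 0.81,
  "sens_msc_conj": 0.69,
  "spec_msc_conj": 0.96,
  "allcause_mort": {
    "50-54": 0.0045,
    "55-59": 0.0065,
    "60-64": 0.0108,
    "65-69": 0.0188,
    "70-74": 0.0336,
    "75-79": 0.054
  },
  "lc_mort_per_100k": {
    "50-54": 28.81,
    "55-59": 52.86,
    "60-64": 101.93,
    "65-69": 153.34,
    "70-74": 248.57
  },
  "stage_prog": {
    "CIS.StageI": 0.098,
    "StageI.StageII": 0.3682,
    "StageI.StageIII": 0.0328,
    "StageI.StageIV": 0.0745,
    "StageII.StageIII": 0.226,
    "StageII.StageIV": 0.151,
    "StageIII.StageIV": 0.1455
  },
  "stage_death": {
    "CIS": 0,
    "StageI": 0.1739,
    "StageII": 0.2842,
    "StageIII": 0.4626,
    "StageIV": 0.588
  },
  "utility": {
    "CIS": 0.87,
    "StageI": 0.84,
    "StageII": 0.84,
    "StageIII": 0.87,
    "StageIV": 0.75
  },
  "utility_normal": 1,
  "utility_death": 0,
  "cost_ldct": 245.86,
  "cost_msc": 400,
  "cost_prediag": 628.36,
  "cost_biopsy": 1232.44,
  "cost_treat": {
    "CIS": 47341.85,
    "StageI": 53344.51,
    "StageII": 83365.95,
    "StageIII": 90643.18,
    "StageIV": 116471.34
  },
  "maintenance_fraction": 0.1,
  "discount_rate": 0.05,
  "cycle_length": 1,
  "max_age": 79,
  "stop_screen_age": 74,
  "wtp_gdp": 70892,
  "price_year": 2018,
  "cpi_rate": 0.02,
  "eligible_fraction_20py": 0.2,
  "eligible_fraction_30py": 0.12,
  "clinical_stage_dist": {
    "CIS": 0,
    "StageI": 0.037,
    "StageII": 0.6852,
    "StageIII": 0.037,
    "StageIV": 0.2408
  },
  "male_fraction": 0.5,
  "options": {
    "rate_conversion": "linear",
    "subtract_lc_mortality": false,
    "recurrence_prob": 0,
    "fp_workup": "prediag",
    "discount_effects": true,
    "half_cycle_correction": false,
    "maintenance_utility": "stage"
  }
}
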