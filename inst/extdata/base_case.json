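{
  "epidemiology": {
    "cap_incidence": {
      "base": 38,
      "low": 25,
      "high": 45
    },
    "cap_mortality": {
      "base": 11.22,
      "low": 11.22,
      "high": 11.22
    },
    "men_incidence": {
      "base": 0.21,
      "low": 0.11,
      "high": 0.52
    },
    "men_mortality": {
      "base": 0.08,
      "low": 0.08,
      "high": 0.08
    },
    "natural_mortality": {
      "base": 6.25,
      "low": 6.25,
      "high": 6.25
    },
    "serotype_coverage": {
      "base": 0.966,
      "low": 0.966,
      "high": 0.966
    }
  },
  "vaccine": {
    "ve_pneumonia": {
      "base": 0.773,
      "low": 0.628,
      "high": 0.918
    },
    "ve_meningitis": {
      "base": 0.59,
      "low": 0.44,
      "high": 0.7
    },
    "coverage_free": {
      "base": 0.1343,
      "low": 0.1343,
      "high": 0.1413
    },
    "coverage_self": {
      "base": 0.0385,
      "low": 0.019,
      "high": 0.058
    },
    "wastage": {
      "base": 0,
      "low": 0.013,
      "high": 0.0168
    },
    "ae_incidence": {
      "base": 0.53,
      "low": 0.53,
      "high": 0.53
    }
  },
  "costs": {
    "cap_hospitalization": {
      "base": 10250,
      "low": 8500,
      "high": 12000
    },
    "men_hospitalization": {
      "base": 39974,
      "low": 21836,
      "high": 46825
    },
    "caregiver_daily": {
      "base": 120,
      "low": 120,
      "high": 120
    },
    "caregiver_days": {
      "base": 10,
      "low": 10,
      "high": 10
    },
    "ae_cost": {
      "base": 7155.21,
      "low": 5366.4075,
      "high": 8944.0125
    },
    "vaccine_price": {
      "base": 166,
      "low": 166,
      "high": 166
    },
    "consumables_per_dose": {
      "base": 32,
      "low": 32,
      "high": 32
    },
    "service_per_dose": {
      "base": 10.14,
      "low": 10.14,
      "high": 10.14
    },
    "cny_per_usd": {
      "base": 7.17,
      "low": 7.17,
      "high": 7.17
    }
  },
  "settings": {
    "discount_rate": {
      "base": 0.03,
      "low": 0.03,
      "high": 0.05
    },
    "horizon_years": 5,
    "cycle_years": 1,
    "population": 1367900,
    "currency_out": "USD",
    "serotype_switch": false,
    "rate_conversion": "linear"
  }
}
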