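# Base-case configuration: single-dose PPV23 programme for adults >= 60,
# Nanning (Guangxi). Rates are per 100,000 person-years unless noted;
# natural mortality is per 1,000; money in CNY; proportions on [0, 1].
# Ranged parameters are {base, low, high}; low/high omitted means no range.
epidemiology:
  cap_incidence: {base: 38, low: 25, high: 45}          # hospitalized CAP, /100,000/yr
  cap_mortality: {base: 11.22}                           # CAP deaths, /100,000/yr
  men_incidence: {base: 0.21, low: 0.11, high: 0.52}     # pneumococcal meningitis, /100,000/yr
  men_mortality: {base: 0.08}                            # meningitis deaths, /100,000/yr
  natural_mortality: {base: 6.25}                        # all-cause, per 1,000/yr
  serotype_coverage: {base: 0.966}                       # PPV23 serotype coverage
vaccine:
  ve_pneumonia: {base: 0.773, low: 0.628, high: 0.918}   # single-dose efficacy vs pneumonia
  ve_meningitis: {base: 0.59, low: 0.44, high: 0.70}     # single-dose efficacy vs meningitis
  coverage_free: {base: 0.1343, low: 0.1343, high: 0.1413}
  coverage_self: {base: 0.0385, low: 0.019, high: 0.058}
  # Base 0 reproduces the procurement accounting with wastage excluded; the
  # published range is kept for sensitivity runs (base outside range is
  # reported as a validation warning, not an error).
  wastage: {base: 0, low: 0.013, high: 0.0168}
  ae_incidence: {base: 0.53}                             # severe adverse events, /100,000 doses
costs:
  cap_hospitalization: {base: 10250, low: 8500, high: 12000}  # CNY per episode
  men_hospitalization: {base: 39974, low: 21836, high: 46825} # CNY per episode
  caregiver_daily: {base: 120}                           # CNY per caregiver-day
  caregiver_days: {base: 10}                             # caregiver-days per episode
  ae_cost: {base: 7155.21, low: 5366.4075, high: 8944.0125}   # CNY per severe event (+/- 25%)
  vaccine_price: {base: 166}                             # CNY per dose
  consumables_per_dose: {base: 32}                       # cold chain + consumables, CNY
  service_per_dose: {base: 10.14}                        # delivery service, CNY
  cny_per_usd: {base: 7.17}
settings:
  discount_rate: {base: 0.03, low: 0.03, high: 0.05}     # annual, applied to benefits
  horizon_years: 5
  cycle_years: 1
  population: 1367900                                    # adults >= 60
  currency_out: USD
  serotype_switch: false                                 # multiply efficacy by serotype coverage
  rate_conversion: linear                                # or "exponential": 1 - exp(-r)
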