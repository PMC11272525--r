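# Default model configuration: first-line advanced squamous NSCLC,
# camrelizumab+paclitaxel+carboplatin (CTC) vs sintilimab+gemcitabine+platinum (SGP),
# Chinese payer perspective. All monetary values are USD (converted from CNY at
# the rate recorded in metadata). Times in months unless a field says otherwise.
metadata:
  currency: USD
  cny_per_usd: 6.73
  reference_arm: CTC
  comparator_arm: SGP

settings:
  cycle_length_days: 21          # one administration interval
  n_cycles: 173                  # ~10-year horizon
  annual_discount: 0.05
  wtp_low: 12734                 # 1x 2022 GDP per capita, USD/QALY
  wtp_high: 38202                # 3x
  cycle_eval: midpoint           # half-cycle correction
  ae_cost_timing: per_cycle
  ae_disutility_timing: induction   # acute toxicity window = cytotoxic cycles
  hr_direction: divide           # comparator hazard = reference hazard / HR
  hr_sampling: lognormal         # PSA: normal on the log-HR scale

# Reference-arm (CTC) Weibull curves, S(t) = exp(-scale * t^shape), t in months
survival:
  pfs: {scale: 0.04, shape: 1.28}
  os:  {scale: 0.01, shape: 1.53}

# Pooled hazard ratios, reference (CTC) vs comparator (SGP)
hazard_ratios:
  pfs: {baseline: 0.75, low: 0.60, high: 0.94}
  os:  {baseline: 0.95, low: 0.71, high: 1.28}

discount_range: {low: 0.03, high: 0.08}   # one-way DSA bounds for the rate

# Per-cycle drug acquisition costs, USD (typical patient, BSA 1.73 m^2)
drug_costs:
  camrelizumab: {baseline: 382.86, low: 306.29, high: 459.43}
  sintilimab:   {baseline: 320.95, low: 256.76, high: 385.14}
  carboplatin:  {baseline: 46.00,  low: 28.17,  high: 149.78}
  cisplatin:    {baseline: 17.83,  low: 9.36,   high: 413.97}
  gemcitabine:  {baseline: 50.55,  low: 38.51,  high: 728.69}
  paclitaxel:   {baseline: 936.11, low: 101.04, high: 1042.47}

# Grade >=3 adverse events (plus grade-2 RCCEP): shared management costs and
# disutilities, arm-specific incidences.
adverse_events:
  - name: neutrophil_count_decreased
    cost:       {baseline: 115.01, low: 51.11, high: 357.80}
    disutility: {baseline: 0.20, low: 0.16, high: 0.24}
    incidence:
      CTC: {baseline: 0.55, low: 0.44, high: 0.66}
      SGP: {baseline: 0.49, low: 0.392, high: 0.588}
  - name: white_blood_cell_count_decreased
    cost:       {baseline: 115.01, low: 51.11, high: 357.80}
    disutility: {baseline: 0.20, low: 0.16, high: 0.24}
    incidence:
      CTC: {baseline: 0.30, low: 0.24, high: 0.36}
      SGP: {baseline: 0.36, low: 0.288, high: 0.432}
  - name: anemia
    cost:       {baseline: 138.75, low: 106.73, high: 160.10}
    disutility: {baseline: 0.11, low: 0.088, high: 0.132}
    incidence:
      CTC: {baseline: 0.10, low: 0.08, high: 0.12}
      SGP: {baseline: 0.34, low: 0.272, high: 0.408}
  - name: platelet_count_decreased
    cost:       {baseline: 1505.92, low: 1240.17, high: 1771.67}
    disutility: {baseline: 0.07, low: 0.056, high: 0.084}
    incidence:
      CTC: {baseline: 0.07, low: 0.056, high: 0.084}
      SGP: {baseline: 0.45, low: 0.36, high: 0.54}
  - name: infectious_pneumonitis
    cost:       {baseline: 242.83, low: 77.56, high: 2644.56}
    disutility: {baseline: 0.05, low: 0.04, high: 0.06}
    incidence:
      CTC: {baseline: 0.04, low: 0.032, high: 0.048}
      SGP: {baseline: 0.14, low: 0.112, high: 0.168}
  - name: rccep
    cost:       {baseline: 467.64, low: 327.35, high: 654.70}
    # as printed in the source table; baseline sits below the stated range
    disutility: {baseline: 0.10, low: 0.16, high: 0.24}
    incidence:
      CTC: {baseline: 0.11, low: 0.088, high: 0.132}
      SGP: {baseline: 0.0, low: 0.0, high: 0.0}

utilities:
  pfs: {baseline: 0.75, low: 0.71, high: 0.85}
  pd:  {baseline: 0.59, low: 0.47, high: 0.71}

strategies:
  CTC:
    induction_drugs: [camrelizumab, paclitaxel, carboplatin]
    maintenance_drug: camrelizumab
    maintenance_cap_months: 24
    n_induction_cycles: 6
  SGP:
    induction_drugs: [sintilimab, gemcitabine, cisplatin]
    maintenance_drug: sintilimab
    maintenance_cap_months: 24
    n_induction_cycles: 6
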