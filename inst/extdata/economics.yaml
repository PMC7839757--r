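# Scalar economic and model constants (annual cycle, lifetime horizon).
disability_weights:
  untreated: 0.42
  treated_seizure_free: 0.072
  treated_with_seizures: 0.319
  adherent_seizure_free_share: 0.60
relapse_split_to_adherent: 0.5
mortality_multiplier_nonadherent: 2.5
mortality_multiplier_adherent: 0.5
exchange_rate_zar_per_intl_dollar: 5.39
gdp_per_capita_intl_dollar: 13215
working_days_per_year_for_daily_gdp: 365
thresholds:
  wtp_intl_dollar: 2154
  gdp_threshold_intl_dollar: 13215
adherence:
  initial_adherent_share: 0.68
  initial_adherent_share_blood_levels: 0.71
  target_adherent_share: 0.90
  ramp_years: 2
program_cost_per_person_year_zar: 443
horizon_cycles: 100
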