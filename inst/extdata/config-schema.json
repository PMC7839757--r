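{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "chwcea scalar configuration (economics.yaml)",
  "type": "object",
  "required": ["disability_weights", "relapse_split_to_adherent",
               "exchange_rate_zar_per_intl_dollar", "gdp_per_capita_intl_dollar",
               "thresholds", "adherence", "program_cost_per_person_year_zar",
               "horizon_cycles"],
  "properties": {
    "disability_weights": {
      "type": "object",
      "required": ["untreated", "treated_seizure_free", "treated_with_seizures",
                   "adherent_seizure_free_share"],
      "properties": {
        "untreated": {"type": "number", "minimum": 0, "maximum": 1},
        "treated_seizure_free": {"type": "number", "minimum": 0, "maximum": 1},
        "treated_with_seizures": {"type": "number", "minimum": 0, "maximum": 1},
        "adherent_seizure_free_share": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "relapse_split_to_adherent": {"type": "number", "minimum": 0, "maximum": 1},
    "mortality_multiplier_nonadherent": {"type": "number", "exclusiveMinimum": 0},
    "mortality_multiplier_adherent": {"type": "number", "exclusiveMinimum": 0},
    "exchange_rate_zar_per_intl_dollar": {"type": "number", "exclusiveMinimum": 0},
    "gdp_per_capita_intl_dollar": {"type": "number", "exclusiveMinimum": 0},
    "working_days_per_year_for_daily_gdp": {"type": "integer", "minimum": 1},
    "thresholds": {
      "type": "object",
      "required": ["wtp_intl_dollar", "gdp_threshold_intl_dollar"],
      "properties": {
        "wtp_intl_dollar": {"type": "number", "exclusiveMinimum": 0},
        "gdp_threshold_intl_dollar": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "adherence": {
      "type": "object",
      "properties": {
        "initial_adherent_share": {"type": "number", "minimum": 0, "maximum": 1},
        "initial_adherent_share_blood_levels": {"type": "number", "minimum": 0, "maximum": 1},
        "target_adherent_share": {"type": "number", "minimum": 0, "maximum": 1},
        "ramp_years": {"type": "integer", "minimum": 0}
      }
    },
    "program_cost_per_person_year_zar": {"type": "number", "minimum": 0},
    "horizon_cycles": {"type": "integer", "minimum": 1}
  }
}
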