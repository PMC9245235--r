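{
  "case_id": "case09",
  "patient": {
    "age": 28,
    "weight": 64,
    "sex": "F",
    "conditions": [
      {
        "code": "pregnancy",
        "pregnancy_weeks": 12
      }
    ]
  },
  "routine": {
    "wake_time": "07:00",
    "sleep_time": "22:00",
    "busy_intervals": [],
    "meal_times": [
      {
        "label": "breakfast",
        "time": "07:30"
      },
      {
        "label": "lunch",
        "time": "12:30"
      },
      {
        "label": "dinner",
        "time": "19:00"
      }
    ]
  },
  "prescription": [
    {
      "drug": "CARBAMAZEPINE 200 MG",
      "dose_amount": 200,
      "doses_per_day": 2,
      "clinical_override_note": "epilepsy crises: risk accepted by clinical decision"
    }
  ],
  "planted": {
    "error_class": "override_risk",
    "expected_alert_types": [
      "contraindication"
    ],
    "expected_feasible": true
  }
}
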