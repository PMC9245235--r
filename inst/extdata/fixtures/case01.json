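{
  "case_id": "case01",
  "patient": {
    "age": 58,
    "weight": 72,
    "sex": "M",
    "conditions": []
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
      "drug": "ASPIRIN 500 MG",
      "dose_amount": 500,
      "doses_per_day": 2
    },
    {
      "drug": "WARFARIN 2.5 MG",
      "dose_amount": 2.5,
      "doses_per_day": 1
    }
  ],
  "planted": {
    "error_class": "nu_pair",
    "expected_alert_types": [
      "nu_interaction"
    ],
    "expected_feasible": true
  }
}
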