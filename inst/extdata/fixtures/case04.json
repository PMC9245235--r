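{
  "case_id": "case04",
  "patient": {
    "age": 67,
    "weight": 65,
    "sex": "F",
    "conditions": []
  },
  "routine": {
    "wake_time": "07:00",
    "sleep_time": "23:00",
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
      "drug": "DIGOXIN 0.25 MG",
      "dose_amount": 0.25,
      "doses_per_day": 1
    },
    {
      "drug": "MYLANTA PLUS",
      "dose_amount": 10,
      "doses_per_day": 3
    }
  ],
  "planted": {
    "error_class": "min_interval",
    "expected_alert_types": [
      "min_interval_needed"
    ],
    "expected_feasible": true
  }
}
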