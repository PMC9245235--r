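{
  "case_id": "case10",
  "patient": {
    "age": 66,
    "weight": 59,
    "sex": "F",
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
      "drug": "ALENDRONATE SODIUM 70 MG",
      "dose_amount": 70,
      "doses_per_day": 1
    },
    {
      "drug": "LEVOTHYROXINE 50 MCG",
      "dose_amount": 50,
      "doses_per_day": 1
    }
  ],
  "planted": {
    "error_class": "specific_guidelines",
    "expected_alert_types": [
      "observation"
    ],
    "expected_feasible": true
  }
}
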