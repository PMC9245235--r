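{
  "case_id": "case07",
  "patient": {
    "age": 45,
    "weight": 68,
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
      "drug": "OMEPRAZOLE 20 MG",
      "dose_amount": 20,
      "doses_per_day": 1
    },
    {
      "drug": "CETIRIZINE 10 MG",
      "dose_amount": 10,
      "doses_per_day": 1
    }
  ],
  "planted": {
    "error_class": "food_relation",
    "expected_alert_types": [
      "food_relation"
    ],
    "expected_feasible": true
  }
}
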