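{
  "case_id": "case08",
  "patient": {
    "age": 6,
    "weight": 20,
    "sex": "F",
    "conditions": []
  },
  "routine": {
    "wake_time": "07:00",
    "sleep_time": "20:00",
    "busy_intervals": [],
    "meal_times": [
      {
        "label": "breakfast",
        "time": "07:30"
      },
      {
        "label": "lunch",
        "time": "12:00"
      },
      {
        "label": "dinner",
        "time": "18:30"
      }
    ]
  },
  "prescription": [
    {
      "drug": "AMOXICILLIN 250 MG",
      "dose_amount": 250,
      "interval_hours": 8
    }
  ],
  "planted": {
    "error_class": "sleep_protection",
    "expected_alert_types": [],
    "expected_feasible": true
  }
}
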