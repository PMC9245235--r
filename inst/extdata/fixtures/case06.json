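{
  "case_id": "case06",
  "patient": {
    "age": 2,
    "weight": 13,
    "sex": "M",
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
      "drug": "AZITHROMYCIN SUSPENSION 200 MG",
      "dose_amount": 200,
      "doses_per_day": 1
    }
  ],
  "planted": {
    "error_class": "overdose",
    "expected_alert_types": [
      "overdose"
    ],
    "expected_feasible": true
  }
}
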