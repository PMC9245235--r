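{
  "case_id": "case05",
  "patient": {
    "age": 61,
    "weight": 78,
    "sex": "M",
    "conditions": [
      {
        "code": "severe_hepatic_disease"
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
      "drug": "ATORVASTATIN CALCIUM 20 MG",
      "dose_amount": 20,
      "doses_per_day": 1
    },
    {
      "drug": "PARACETAMOL 500 MG",
      "dose_amount": 500,
      "doses_per_day": 2
    }
  ],
  "planted": {
    "error_class": "contraindication",
    "expected_alert_types": [
      "contraindication"
    ],
    "expected_feasible": true
  }
}
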